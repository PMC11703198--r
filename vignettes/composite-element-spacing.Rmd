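---
title: "Predicting composite elements from motif spacing preferences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting composite elements from motif spacing preferences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spice)
```

## The problem

Transcription factors often act in pairs: two proteins bind neighbouring
DNA motifs in a constrained geometry — a *composite element* — and the
cooperative complex drives transcription far more potently than either
factor alone. Classic examples are the AP-1/IRF composite element (AICE,
`TGAnTCA` next to a `GAAA` core, spaced 0 or 4 bp apart) and STAT dimers
pairing into tetramers on tandem GAS sites. Because the cooperating
proteins touch each other, the spacing and relative orientation of the two
motifs is tightly constrained; a spike in the spacing distribution of a
motif pair across thousands of ChIP-Seq peaks is therefore strong evidence
for a physical complex.

`spice` screens a ChIP-Seq peak set against a motif database for exactly
this signature and reports, for every candidate partner motif, the most
enriched spacing, its adjusted p-value, and a database-level E-value.

## The procedure

1. **Peaks to windows.** Peaks are ranked by significance (narrowPeak
   column 8, `-log10 p`), the top `n` (1000 by default) are kept, and a
   fixed-width window (500 bp by default) is extracted around each peak
   summit. Windows truncated by a contig end are dropped rather than
   padded, so all windows are identically sized.
2. **Primary motif.** The motif of the ChIP'd factor itself is either
   supplied by name from the database or discovered de novo: the most
   over-represented k-mers seed a ZOOPS (zero-or-one occurrence per
   sequence) expectation–maximisation over both strands, and candidates
   are ranked by their log-likelihood-ratio score against a mononucleotide
   background fitted from the windows. ZOOPS matches the structure of
   summit-centered ChIP-Seq data — one binding site per peak.
3. **Centering.** Every window is scanned on both strands with the primary
   PWM; windows whose best score falls below the threshold are eliminated.
   The rest are reverse-complemented if needed so the match reads on the
   plus strand, and trimmed to equal flanks so the match midpoint sits at
   the window midpoint.
4. **Secondary scan.** For each database motif, the single best-scoring
   non-overlapping placement in each centered window is recorded as a
   (quadrant, gap) bin: upstream/downstream of the primary crossed with
   same/opposite strand, and the edge-to-edge distance in 1-bp bins
   (gap 0 = abutting). No score threshold is applied to the secondary
   site — every retained window contributes exactly one observation, which
   is what makes the null model below exact.
5. **Spacing test.** If secondary placements carry no positional
   preference, each of the `B` legal (quadrant, gap) bins is equally
   likely, because every bin corresponds to exactly one (position, strand)
   placement. A bin observed `k` times among `n` windows is scored with
   the exact binomial tail `P[X >= k]`, `X ~ Binomial(n, 1/B)`, and
   Bonferroni-adjusted over the `B` bins. The pair's E-value multiplies
   the best adjusted p-value by the number of motifs in the database, a
   second Bonferroni level that makes values comparable across motifs of
   different widths.
6. **Grouping and reporting.** Partners above the significance threshold
   (`p_adj < 0.01`) are ranked, redundant motifs (PFM Pearson similarity
   at the best ungapped alignment, both orientations, at least 5 aligned
   columns) are collapsed by single linkage, and many library runs are
   assembled into a primary-by-secondary interaction matrix, rendered as a
   `-log10(E)` heat map after an `E < 1e-10` filter.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `width` (windows) | 500 bp | summit-centered window; also bounds the scanned flank |
| `n` (top peaks) | 1000 | most significant peaks used |
| `min_score_frac` | 0.6 | primary threshold as a fraction of the motif's maximum log-odds score |
| `pseudocount` | 0.01 | PFM smoothing `(p + c*bg)/(1+c)`; keeps PWMs finite |
| `alpha` | 0.01 | ranking threshold on the best bin-adjusted p-value |
| `e_threshold` | 1e-10 | interaction-matrix filter |
| `sim_threshold` | 0.8 | single-linkage similarity for redundancy grouping |
| `margin` | full flank | optional cap on the scanned gap |
| `pool_quadrants` | FALSE | test gaps pooled over the four orientations |

The primary threshold (60% of the maximum achievable score) controls only
which windows survive to the spacing stage; the spacing statistics
condition on the retained set, so mild changes move `n`, not the null
model. Quadrant-separate testing is the default because protein contacts
are usually orientation-specific; pooling is available when orientation is
irrelevant and costs a factor 4 in bins.

## Numerical and design choices

* **Coordinates.** File formats are BED-convention 0-based half-open;
  in-memory R objects are 1-based. Gaps are edge-to-edge (0 = abutting),
  which makes the "0 bp" AICE spacing meaningful.
* **Alphabet.** Fixed to A,C,G,T with complement permutation (T,G,C,A);
  placements touching any other letter are unscoreable and can never be a
  best site.
* **Ties.** All ties break deterministically: best primary — leftmost,
  then plus strand; best secondary — smaller gap, then upstream, then same
  strand; best bin — smaller p, then smaller gap, then quadrant order.
  Scores are compared after rounding to 9 decimals so that two placements
  with identical letters (whose floating-point sums may differ by an ulp
  through summation order) tie exactly and the deterministic rule decides.
* **Binomial tails** are computed with `stats::pbinom`, which is exact;
  the test suite checks them against an independent log-space term
  summation to below 1e-9 relative error up to `n = 5000`.
* **E-values** are floored at 1e-300 before the `-log10` transform in the
  heat map to avoid infinities; empty cells are rendered as background,
  not as zero, so "not significant" stays distinct from "E near 1".
* **Self-pairing** (tetramer-style analysis) needs no special casing: the
  overlap-exclusion rule removes the primary's own site from the
  secondary scan.
* **EM details.** The ZOOPS likelihood uses a uniform position/strand
  prior given a site; on the minus strand position `j` of the motif emits
  the complement of the observed base while the background term stays that
  of the observed base. The M-step adds a negligible (1e-8) pseudocount to
  keep the PFM strictly positive; the log-likelihood trace is
  non-decreasing and iteration stops on a change below `tol` (1e-4) or at
  `max_iter`, returning the best-so-far model with a flag rather than an
  error. On motif-free data the fitted motif converges toward chance
  k-mer structure; the enrichment score per window then sits near zero,
  but the site prior itself is weakly identified (the likelihood is almost
  flat in it once the motif is background-like), so score — not the
  prior — is the quantity to gate on.

## The synthetic-data generator

`plant_spec()`/`generate()` emulate the data structure the pipeline
assumes: summit-centered windows over an i.i.d. (or first-order Markov)
background, a primary site planted at the center (optionally jittered) on
a random strand, and in a chosen fraction of windows a secondary site at
an exact edge-to-edge gap in a chosen quadrant relative to the primary's
orientation. Presets reproduce the validated composite-element geometries:
`generate_aice()` (AP-1 `TGASTCA` + IRF `GAAA` core at gaps 0 and 4),
`generate_gas_tetramer()` (two GAS `TTCNNNGAA` sites, 11 bp apart), and
`generate_ctcf_ets()` (CTCF-like core + ETS `GGAA` site, 8 bp apart),
each planting the partner in 60% of 1000 windows by default — effect
sizes at which a real composite element is unmistakable, while the
remaining 40% of windows behave as null background.

Two generator choices deserve comment. Site letters are sampled from the
motif's PFM by default (a `consensus_only` switch produces literal
plants for exact-recovery tests), so score thresholds are genuinely
exercised. And consensus-derived PFMs assign deliberately *generic*
column probabilities — the consensus strength decays slightly along the
motif and within-column shares are unequal — because a PFM whose columns
repeat identical values produces exactly tied best-site scores at many
placements, and any deterministic tie-break then concentrates those ties
in particular bins and biases the spacing null. Real database PFMs are
generic in this sense; the generator mirrors that.

What the generator does not emulate: read-level noise, peak-calling
artefacts, copy-number or mappability biases, clustered homotypic sites,
and realistic inter-peak sequence composition. Passing the planted-
recovery tests therefore demonstrates the correctness of the machinery
and the calibration of the statistics under the stated null, not
performance on any particular organism's genome.

## Problem sizes and validation

The packaged validation runs at desk scale: spacing recovery uses 1000
windows of 500 bp per scenario (AICE at gaps 4 and 0, GAS tetramer at
11 bp, CTCF/ETS at 8 bp), and the null calibration uses 500 replicates of
500 windows each, checking that the fraction of null replicates with any
bin-adjusted p-value below 0.01 stays at or below 0.01 (the Bonferroni
bound plus binomial discreteness make the test conservative). The
genome-scale screens the method is meant for (hundreds of ENCODE
libraries against a full motif database) are a matter of looping
`analyze_library()` over libraries and feeding `build_matrix()`; they are
not reproduced in the package's own tests because they require the
external datasets.

## Known limitations

* The uniform-placement null ignores sequence composition structure
  (e.g. CpG islands, repeats) that can make some placements intrinsically
  better-scoring; a dinucleotide or position-aware null is out of scope.
* One observation per window means dense homotypic clusters contribute
  only their best site.
* The de novo stage is a single-motif ZOOPS EM; gapped or multi-part
  primary motifs (as a dedicated discovery tool would model) are not
  searched.
* Motif similarity is a PFM correlation, not a statistical comparison
  with p-values; the 0.8 single-linkage threshold is a pragmatic family
  grouping, and a curated family map can be substituted where available.

## A worked example

```{r example}
db <- preset_motifs()
sim <- generate_aice(600, seed = 7)
fit <- analyze_pair(sim$windows, db[["AP1"]], db[["IRF"]])
fit
```

The best bin sits at one of the two planted gaps on the same strand
downstream — the AICE geometry. Screening the whole preset database ranks
the true partner first and assigns it the only extreme E-value:

```{r screen}
scr <- analyze_library(sim$windows, db[["AP1"]], db)
scr$significant
```

```{r bars, fig.width = 6, fig.height = 3.5}
plot(fit)
```
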