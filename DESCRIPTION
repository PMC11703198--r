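Package: spice
Title: Spacing Preference Identification of Composite Elements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts transcription-factor composite elements and preferred
    motif spacings from ChIP-Seq peaks. Peak sequences are centered and
    strand-oriented on the best match of a primary motif (discovered de novo
    by ZOOPS expectation-maximisation or supplied by the user), candidate
    partner motifs from a database are scanned in the flanks, and the
    edge-to-edge spacing distribution of best secondary sites is tested
    bin-wise with an exact binomial test against a uniform-placement null,
    Bonferroni-adjusted over bins. Motif pairs are scored with E-values,
    redundant partners are clustered by matrix similarity, and results are
    aggregated into primary-by-secondary interaction matrices with heat map
    and spacing bar-graph output. Includes a planted-composite-element
    simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    igraph,
    grDevices,
    graphics,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
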