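# Spacing analysis: center windows on the best primary-motif match, scan
# for each secondary motif's best non-overlapping site, histogram the
# (quadrant, gap) placements, and test bin-wise enrichment with an exact
# binomial tail against the uniform-placement null.
#
# Geometry. After centering, a window carries its primary match on the plus
# strand at primary_span = [p_start, p_end] (1-based, inclusive) with equal
# flanks on both sides. A secondary placement is summarised by its quadrant
# (upstream/downstream of the primary x same/opposite strand) and its
# edge-to-edge gap in bp (0 = abutting). Each legal (position, strand)
# placement maps to exactly one (quadrant, gap) bin, so the uniform null
# assigns probability 1/B to each of the B bins.

.QUADRANTS <- c("upstream-same", "upstream-opposite",
                "downstream-same", "downstream-opposite")

#' Best primary-motif match per window
#'
#' Scans every position of every window on both strands with the primary
#' motif's log-odds matrix and keeps the single highest-scoring placement;
#' ties are broken by leftmost position, then plus strand. Windows whose
#' best score falls below the score threshold are reported unmatched.
#'
#' @param windows A [window_set()].
#' @param primary A [motif_model()].
#' @param min_score Absolute log-odds threshold; when `NULL`,
#'   `min_score_frac * motif_max_score(primary)` is used.
#' @param min_score_frac Fraction of the maximum achievable score (default
#'   0.6) used when `min_score` is `NULL`.
#' @return A `data.frame` with one row per window: `id`, `position` (1-based
#'   start of the match), `strand`, `score`, `matched`. Unmatched windows
#'   have `NA` position/strand/score.
#' @export
find_best_primary <- function(windows, primary, min_score = NULL,
                              min_score_frac = 0.6) {
  stopifnot(inherits(primary, "motif_model"))
  if (is.null(min_score)) min_score <- min_score_frac * motif_max_score(primary)
  n <- nrow(windows)
  out <- data.frame(id = windows$id, position = NA_integer_,
                    strand = NA_character_, score = NA_real_,
                    matched = FALSE, stringsAsFactors = FALSE)
  if (!n) return(out)
  lens <- nchar(windows$seq)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    if (L < primary$width) next
    bm <- best_match_codes(seq_code_matrix(windows$seq[idx]), primary)
    out$position[idx] <- bm$position
    out$strand[idx] <- bm$strand
    out$score[idx] <- bm$score
  }
  out$matched <- !is.na(out$score) & out$score >= min_score & is.finite(out$score)
  out$position[!out$matched] <- NA_integer_
  out$strand[!out$matched] <- NA_character_
  out$score[!out$matched] <- NA_real_
  attr(out, "motif_width") <- primary$width
  out
}

#' Center and strand-orient windows on their primary match
#'
#' Windows matched on the minus strand are reverse-complemented first, so the
#' primary site always reads on the plus strand of the output. The sequence
#' is then trimmed to equal flanks around the primary match (the shorter of
#' the two original flanks on each side), which places the primary midpoint
#' exactly at the window midpoint without padding; the output length is at
#' most the input length.
#'
#' @param windows A [window_set()].
#' @param matches Output of [find_best_primary()] for the same windows.
#' @return A `data.frame` of class `centered_windows` with columns `id`,
#'   `seq`, `p_start`, `p_end` (1-based inclusive primary span), `flank`.
#'   Unmatched windows are dropped.
#' @export
center_and_orient <- function(windows, matches) {
  keep <- which(matches$matched)
  if (!length(keep)) {
    out <- data.frame(id = character(), seq = character(),
                      p_start = integer(), p_end = integer(),
                      flank = integer(), stringsAsFactors = FALSE)
    class(out) <- c("centered_windows", "data.frame")
    return(out)
  }
  seqs <- windows$seq[keep]
  pos <- matches$position[keep]
  strand <- matches$strand[keep]
  L <- nchar(seqs)
  w <- attr(matches, "motif_width")
  if (is.null(w)) {
    # infer: the width is shared; recover it from any window geometry is not
    # possible, so carry it through the matches attribute or recompute here.
    stop("matches must carry the primary motif width ",
         "(use find_best_primary output unmodified)")
  }
  neg <- strand == "-"
  if (any(neg)) {
    seqs[neg] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[neg])))
    pos[neg] <- L[neg] - (pos[neg] + w - 1L) + 1L
  }
  flank <- pmin(pos - 1L, L - (pos + w - 1L))
  from <- pos - flank
  to <- pos + w - 1L + flank
  out <- data.frame(id = windows$id[keep],
                    seq = substring(seqs, from, to),
                    p_start = flank + 1L, p_end = flank + w,
                    flank = flank, stringsAsFactors = FALSE)
  class(out) <- c("centered_windows", "data.frame")
  out
}

#' Best secondary site and its spacing bin per centered window
#'
#' Scans both strands of each centered window with the secondary motif and
#' takes the single best-scoring placement whose span does not overlap the
#' primary span (for self-pairing this automatically excludes the primary's
#' own site). No score threshold is applied: whenever a legal placement
#' exists the best one is taken, mirroring the uniform-placement null. Ties
#' are broken by smaller gap, then upstream before downstream, then same
#' strand before opposite.
#'
#' @param cw A `centered_windows` object from [center_and_orient()].
#' @param secondary A [motif_model()].
#' @param margin Restrict the scan to placements with gap at most `margin`
#'   bp from the primary (default: the full retained flank).
#' @return A `data.frame` with one row per centered window: `id`, `quadrant`,
#'   `gap`, `score` (`NA` where no legal placement exists).
#' @export
scan_secondary_best <- function(cw, secondary, margin = Inf) {
  stopifnot(inherits(secondary, "motif_model"))
  ws <- secondary$width
  out <- data.frame(id = cw$id,
                    quadrant = rep(NA_character_, nrow(cw)),
                    gap = rep(NA_integer_, nrow(cw)),
                    score = rep(NA_real_, nrow(cw)),
                    stringsAsFactors = FALSE)
  if (!nrow(cw)) return(out)
  lens <- nchar(cw$seq)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    p_start <- cw$p_start[idx[1]]
    p_end <- cw$p_end[idx[1]]
    maxgap <- p_start - 1L - ws        # equal flanks: same bound on each side
    maxgap <- min(maxgap, as.integer(min(margin, .Machine$integer.max)))
    if (maxgap < 0L) next
    sc <- scan_pwm_codes(seq_code_matrix(cw$seq[idx]), secondary)
    g <- 0:maxgap
    s_up <- p_start - ws - g           # upstream start for gap g
    s_dn <- p_end + 1L + g             # downstream start for gap g
    ncand <- 4L * (maxgap + 1L)
    M <- matrix(-Inf, length(idx), ncand)
    # column order encodes the tie-break priority:
    # gap ascending, upstream before downstream, same before opposite
    M[, seq(1L, ncand, by = 4L)] <- sc$plus[, s_up, drop = FALSE]
    M[, seq(2L, ncand, by = 4L)] <- sc$minus[, s_up, drop = FALSE]
    M[, seq(3L, ncand, by = 4L)] <- sc$plus[, s_dn, drop = FALSE]
    M[, seq(4L, ncand, by = 4L)] <- sc$minus[, s_dn, drop = FALSE]
    # round for comparison so content-identical sites tie exactly and the
    # deterministic (gap, side, strand) priority decides
    best <- max.col(round(M, 9), ties.method = "first")
    bscore <- M[cbind(seq_along(idx), best)]
    ok <- is.finite(bscore)
    quad_id <- (best - 1L) %% 4L + 1L
    quad <- c("upstream-same", "upstream-opposite",
              "downstream-same", "downstream-opposite")[quad_id]
    out$quadrant[idx[ok]] <- quad[ok]
    out$gap[idx[ok]] <- ((best - 1L) %/% 4L)[ok]
    out$score[idx[ok]] <- bscore[ok]
  }
  out
}

#' Build the spacing histogram
#'
#' Counts best-placement observations per (quadrant, gap) bin. `n` is the
#' number of windows contributing a legal placement; `B` is the total number
#' of bins available given the window geometry (union over contributing
#' windows), which equals the number of legal placements per full-flank
#' window.
#'
#' @param placements Output of [scan_secondary_best()].
#' @param cw The `centered_windows` the placements came from.
#' @param secondary_width Width of the scanned secondary motif.
#' @param margin The margin the placements were scanned with, if any.
#' @param pool_quadrants Collapse the four orientation quadrants so bins are
#'   gaps only (each pooled bin then holds 4 placements).
#' @return An object of class `spacing_histogram`: list with `counts`
#'   (data.frame `quadrant`, `gap`, `k`), `n`, `B` (number of legal
#'   placements), and `pooled`.
#' @export
spacing_histogram <- function(placements, cw, secondary_width,
                              margin = Inf, pool_quadrants = FALSE) {
  obs <- placements[!is.na(placements$gap), , drop = FALSE]
  n <- nrow(obs)
  max_gap <- if (n)
    min(max(cw$flank[match(obs$id, cw$id)]) - secondary_width, margin) else
    -1L
  B <- if (n) 4L * (as.integer(max_gap) + 1L) else 0L
  if (pool_quadrants && n) obs$quadrant <- "pooled"
  counts <- if (n) {
    agg <- stats::aggregate(list(k = rep(1L, n)),
                            by = list(quadrant = obs$quadrant, gap = obs$gap),
                            FUN = sum)
    agg[order(match(agg$quadrant, c(.QUADRANTS, "pooled")), agg$gap), ,
        drop = FALSE]
  } else data.frame(quadrant = character(), gap = integer(), k = integer())
  rownames(counts) <- NULL
  structure(list(counts = counts, n = n, B = B, pooled = pool_quadrants),
            class = "spacing_histogram")
}

#' @export
print.spacing_histogram <- function(x, ...) {
  cat("<spacing_histogram> n =", x$n, " windows over B =", x$B, "bins;",
      nrow(x$counts), "occupied\n")
  invisible(x)
}

#' Bin-wise binomial enrichment test of the spacing histogram
#'
#' For every occupied bin the raw p-value is the exact upper binomial tail
#' `P[X >= k]` with `X ~ Binomial(n, 1/B)`; the adjusted p-value is the
#' Bonferroni correction `min(1, B * p_raw)` over the `B` bins tested.
#' For a pooled histogram each gap bin holds the 4 quadrant placements, so
#' the bin probability is `4/B` and the correction spans `B/4` bins.
#'
#' @param hist A [spacing_histogram()].
#' @return A `data.frame` with columns `quadrant`, `gap`, `k`, `p_raw`,
#'   `p_adj`, ordered by increasing `p_adj` (ties: smaller gap, then
#'   quadrant order).
#' @export
binomial_spacing_test <- function(hist) {
  stopifnot(inherits(hist, "spacing_histogram"))
  if (hist$B < 1L) stop("histogram has no available bins (B = 0)")
  if (hist$n < 1L) stop("histogram has no observations (n = 0)")
  res <- hist$counts
  pooled <- isTRUE(hist$pooled)
  p_bin <- if (pooled) 4 / hist$B else 1 / hist$B
  n_bins <- if (pooled) hist$B %/% 4L else hist$B
  res$p_raw <- stats::pbinom(res$k - 1L, hist$n, p_bin, lower.tail = FALSE)
  res$p_adj <- pmin(1, n_bins * res$p_raw)
  res <- res[order(res$p_adj, res$gap,
                   match(res$quadrant, c(.QUADRANTS, "pooled"))), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Pair E-value
#'
#' The best bin-adjusted p-value of a motif pair multiplied by the number of
#' secondary motifs in the scanned database (a second Bonferroni level across
#' the library). Not capped at 1.
#'
#' @param best_p_adj Minimal adjusted p-value over spacing bins.
#' @param n_secondary_motifs Database size.
#' @return Numeric E-value.
#' @export
pair_evalue <- function(best_p_adj, n_secondary_motifs) {
  if (n_secondary_motifs < 1) stop("n_secondary_motifs must be >= 1")
  best_p_adj * n_secondary_motifs
}

# internal: spacing analysis of one secondary motif on pre-centered windows
.pair_from_centered <- function(cw, primary, secondary, n_secondary,
                                margin = Inf, pool_quadrants = FALSE) {
  placements <- scan_secondary_best(cw, secondary, margin = margin)
  hist <- spacing_histogram(placements, cw, secondary$width,
                            margin = margin,
                            pool_quadrants = pool_quadrants)
  if (hist$n == 0L) {
    return(structure(list(primary_name = primary$name,
                          secondary_name = secondary$name,
                          empty = TRUE, n = 0L, hist = hist,
                          tests = NULL, best = NULL, evalue = NA_real_),
                     class = "spice_pair"))
  }
  tests <- binomial_spacing_test(hist)
  best <- tests[1L, , drop = FALSE]
  structure(list(primary_name = primary$name, secondary_name = secondary$name,
                 empty = FALSE, n = hist$n, hist = hist, tests = tests,
                 best = best,
                 evalue = pair_evalue(best$p_adj, n_secondary),
                 n_secondary = n_secondary),
            class = "spice_pair")
}

#' Spacing analysis of one primary/secondary motif pair
#'
#' Composes the full per-pair pipeline: find the best primary match in every
#' window, drop windows without one, center and strand-orient on the match,
#' scan for the best non-overlapping secondary site, histogram the
#' (quadrant, gap) placements, and test each occupied 1-bp bin with the
#' exact binomial tail against the uniform null, Bonferroni-adjusted over
#' bins. The reported best bin has the minimal adjusted p-value (ties:
#' smaller gap, then quadrant order); the pair E-value multiplies it by
#' `n_secondary` (the database size the pair was drawn from).
#'
#' @param windows A [window_set()].
#' @param primary,secondary [motif_model()] objects; `secondary` may equal
#'   `primary` for self-pairing (tetramer-style) analysis, in which case the
#'   primary's own site is excluded by the overlap rule.
#' @param min_score,min_score_frac Primary match threshold, see
#'   [find_best_primary()].
#' @param n_secondary Number of motifs in the database the secondary came
#'   from (1 for a standalone pair), used for the E-value.
#' @param margin Restrict the secondary scan to gaps of at most `margin` bp.
#' @param pool_quadrants Test gaps pooled over the four orientation
#'   quadrants instead of quadrant-separately.
#' @return An object of class `spice_pair`: list with `primary_name`,
#'   `secondary_name`, `n` (windows contributing), `hist`, `tests`, `best`
#'   (one-row data.frame), `evalue`, and `empty` (`TRUE` when no window
#'   retained a primary match — reported as a flag, not an error).
#' @examples
#' sim <- generate_aice(200, seed = 1)
#' ap1 <- motif_from_consensus("AP1", "TGASTCA")
#' irf <- motif_from_consensus("IRF", "AANTGAAA")
#' fit <- analyze_pair(sim$windows, ap1, irf)
#' fit
#' @export
analyze_pair <- function(windows, primary, secondary, min_score = NULL,
                         min_score_frac = 0.6, n_secondary = 1L,
                         margin = Inf, pool_quadrants = FALSE) {
  if (!nrow(windows)) stop("no windows supplied")
  matches <- find_best_primary(windows, primary, min_score, min_score_frac)
  cw <- center_and_orient(windows, matches)
  .pair_from_centered(cw, primary, secondary, n_secondary,
                      margin = margin, pool_quadrants = pool_quadrants)
}

#' @export
print.spice_pair <- function(x, ...) {
  cat("<spice_pair> ", x$primary_name, " x ", x$secondary_name, "\n", sep = "")
  if (x$empty) {
    cat("  no windows retained a primary match\n")
    return(invisible(x))
  }
  cat(sprintf("  n = %d windows, B = %d bins\n", x$n, x$hist$B))
  cat(sprintf("  best spacing: gap %d (%s), k = %d, p_adj = %.3g, E = %.3g\n",
              x$best$gap, x$best$quadrant, x$best$k, x$best$p_adj, x$evalue))
  invisible(x)
}

#' @method summary spice_pair
#' @export
summary.spice_pair <- function(object, n_top = 5L, ...) {
  print(object)
  if (!object$empty) {
    cat("  top bins:\n")
    print(utils::head(object$tests, n_top))
  }
  invisible(object)
}

#' Spacing bar graph of a pair result
#'
#' Bars show the number of windows whose best secondary site fell at each
#' gap (summed over quadrants by default); the most significant bin is
#' highlighted in red.
#'
#' @param x A `spice_pair`.
#' @param quadrant `"all"` to pool quadrants for display, or one quadrant
#'   label to restrict.
#' @param ... Passed to [graphics::barplot()].
#' @method plot spice_pair
#' @export
plot.spice_pair <- function(x, quadrant = "all", ...) {
  if (x$empty || x$n == 0L) stop("empty pair result: nothing to plot")
  cnt <- x$hist$counts
  if (quadrant != "all") cnt <- cnt[cnt$quadrant == quadrant, , drop = FALSE]
  gaps <- 0:max(cnt$gap)
  k <- vapply(gaps, function(g) sum(cnt$k[cnt$gap == g]), integer(1))
  col <- ifelse(gaps == x$best$gap, "red", "grey60")
  graphics::barplot(k, names.arg = gaps, col = col, border = NA,
                    xlab = "edge-to-edge gap (bp)",
                    ylab = "windows with best secondary site",
                    main = paste(x$primary_name, "x", x$secondary_name), ...)
  invisible(x)
}

#' Screen a motif database for spacing-constrained partners
#'
#' Runs [analyze_pair()] for every motif in the database against a common
#' primary (the primary matching and window centering are computed once),
#' computes E-values against the database size, keeps pairs whose best
#' adjusted p-value passes `alpha`, and ranks them by increasing p-value.
#'
#' @param windows A [window_set()].
#' @param primary A [motif_model()].
#' @param db A [motif_db()] of secondary motifs.
#' @param alpha Significance threshold on the best bin-adjusted p-value
#'   (default 0.01, the pipeline's ranking threshold).
#' @inheritParams analyze_pair
#' @return An object of class `spice_screen`: list with `table` (all pairs,
#'   ranked), `significant` (subset with `p_adj < alpha`), `pairs` (the
#'   underlying `spice_pair` objects, named by secondary), `primary_name`,
#'   `alpha`, `n_windows`.
#' @export
analyze_library <- function(windows, primary, db, alpha = 0.01,
                            min_score = NULL, min_score_frac = 0.6,
                            margin = Inf, pool_quadrants = FALSE) {
  stopifnot(inherits(db, "motif_db"))
  if (!length(db)) stop("empty motif database")
  matches <- find_best_primary(windows, primary, min_score, min_score_frac)
  cw <- center_and_orient(windows, matches)
  pairs <- lapply(db$motifs, function(sec)
    .pair_from_centered(cw, primary, sec, n_secondary = length(db),
                        margin = margin, pool_quadrants = pool_quadrants))
  rows <- lapply(pairs, function(p) {
    if (p$empty) return(NULL)
    data.frame(primary = p$primary_name, secondary = p$secondary_name,
               quadrant = p$best$quadrant, gap = p$best$gap, k = p$best$k,
               n = p$n, B = p$hist$B, p_raw = p$best$p_raw,
               p_adj = p$best$p_adj, evalue = p$evalue,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(primary = character(), secondary = character(),
                      quadrant = character(), gap = integer(), k = integer(),
                      n = integer(), B = integer(), p_raw = numeric(),
                      p_adj = numeric(), evalue = numeric())
  tab <- tab[order(tab$p_adj, tab$gap, tab$secondary), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 significant = tab[tab$p_adj < alpha, , drop = FALSE],
                 pairs = pairs, primary_name = primary$name, alpha = alpha,
                 n_windows = nrow(windows), n_matched = sum(matches$matched)),
            class = "spice_screen")
}

#' @export
print.spice_screen <- function(x, ...) {
  cat("<spice_screen> primary ", x$primary_name, ": ",
      nrow(x$table), " pairs tested, ", nrow(x$significant),
      " significant at p_adj < ", x$alpha, "\n", sep = "")
  if (nrow(x$significant)) print(utils::head(x$significant, 10L))
  invisible(x)
}

#' @method summary spice_screen
#' @export
summary.spice_screen <- function(object, ...) {
  cat(sprintf("windows: %d input, %d with a primary match\n",
              object$n_windows, object$n_matched))
  print(object)
  invisible(object)
}

#' @method as.data.frame spice_screen
#' @export
as.data.frame.spice_screen <- function(x, ...) x$table
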