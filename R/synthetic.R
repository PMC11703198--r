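# Planted-composite-element simulator: summit-style windows drawn from an
# i.i.d. or first-order Markov background, a primary motif site planted at
# the window center (+/- jitter) on a random strand, and, in a chosen
# fraction of windows, a secondary site planted at an exact edge-to-edge gap
# in a chosen quadrant relative to the primary's orientation. Every window
# is accompanied by a truth record.

.BASES_CHR <- c("A", "C", "G", "T")

#' Plant specification
#'
#' @param n_windows Number of windows.
#' @param window_width Window width in bp (default 500, the summit-centered
#'   window used throughout the pipeline).
#' @param background Either 4 mononucleotide frequencies (A,C,G,T) or a 4x4
#'   first-order Markov transition matrix (rows = current base).
#' @param primary A [motif_model()] or IUPAC consensus string.
#' @param secondary Optional [motif_model()] or consensus string; `NULL`
#'   plants the primary only (null dataset).
#' @param gap Edge-to-edge distance in bp between primary and secondary
#'   sites (0 = abutting).
#' @param quadrant One of `"upstream-same"`, `"upstream-opposite"`,
#'   `"downstream-same"`, `"downstream-opposite"`, relative to the primary's
#'   orientation.
#' @param plant_fraction Fraction of windows receiving a secondary site.
#' @param primary_jitter Maximum absolute offset of the primary site from
#'   the window center, in bp.
#' @param consensus_only Plant literal consensus letters instead of sampling
#'   site letters from the PFM (degenerate IUPAC letters are still sampled
#'   uniformly among their allowed bases).
#' @param rng_seed Integer seed; generation is deterministic given the spec.
#' @return A list of class `plant_spec`.
#' @export
plant_spec <- function(n_windows, window_width = 500L,
                       background = rep(0.25, 4), primary,
                       secondary = NULL, gap = 0L,
                       quadrant = "downstream-same", plant_fraction = 0,
                       primary_jitter = 0L, consensus_only = FALSE,
                       rng_seed = 1L) {
  as_motif <- function(x, nm) {
    if (is.null(x)) return(NULL)
    if (inherits(x, "motif_model")) x else motif_from_consensus(nm, x)
  }
  primary <- as_motif(primary, "primary")
  secondary <- as_motif(secondary, "secondary")
  if (!quadrant %in% .QUADRANTS)
    stop("quadrant must be one of: ", paste(.QUADRANTS, collapse = ", "))
  if (plant_fraction < 0 || plant_fraction > 1)
    stop("plant_fraction must be in [0, 1]")
  if (gap < 0) stop("gap must be >= 0")
  W <- as.integer(window_width)
  wp <- primary$width
  c0 <- (W - wp) %/% 2L + 1L
  j <- as.integer(primary_jitter)
  if (c0 - j < 1L || c0 + j + wp - 1L > W)
    stop("primary motif (with jitter) does not fit in the window")
  if (!is.null(secondary)) {
    ws <- secondary$width
    upstream <- grepl("^upstream", quadrant)
    room <- if (upstream) (c0 - j) - 1L else W - (c0 + j + wp - 1L)
    if (gap + ws > room)
      stop("window cannot contain primary + gap + secondary: need ",
           gap + ws, " bp of flank, have ", room)
  }
  structure(list(n_windows = as.integer(n_windows), window_width = W,
                 background = background, primary = primary,
                 secondary = secondary, gap = as.integer(gap),
                 quadrant = quadrant, plant_fraction = plant_fraction,
                 primary_jitter = j, consensus_only = consensus_only,
                 rng_seed = as.integer(rng_seed)),
            class = "plant_spec")
}

# sample n site code rows (n x width) from a motif model
.sample_sites <- function(motif, n, consensus_only) {
  w <- motif$width
  if (consensus_only) {
    codes <- max.col(motif$pfm, ties.method = "first")
    return(matrix(rep(codes, each = n), n, w))
  }
  matrix(vapply(seq_len(w), function(jj)
    sample.int(4L, n, replace = TRUE, prob = motif$pfm[jj, ]),
    integer(n)), nrow = n)
}

# background code matrix n x W, i.i.d. or first-order Markov
.sample_background <- function(background, n, W) {
  if (is.matrix(background)) {
    if (!all(dim(background) == c(4L, 4L)))
      stop("Markov background must be a 4x4 transition matrix")
    trans <- background / rowSums(background)
    # stationary distribution for the first column
    ev <- eigen(t(trans))
    stat <- abs(Re(ev$vectors[, which.min(abs(ev$values - 1))]))
    stat <- stat / sum(stat)
    m <- matrix(0L, n, W)
    m[, 1L] <- sample.int(4L, n, replace = TRUE, prob = stat)
    cum <- t(apply(trans, 1L, cumsum))
    for (t in 2:W) {
      u <- stats::runif(n)
      cc <- cum[m[, t - 1L], , drop = FALSE]
      m[, t] <- 1L + (u > cc[, 1L]) + (u > cc[, 2L]) + (u > cc[, 3L])
    }
    m
  } else {
    bg <- background / sum(background)
    matrix(sample.int(4L, n * W, replace = TRUE, prob = bg), n, W)
  }
}

#' Generate a planted-composite-element dataset
#'
#' Draws each window from the background model, plants a primary site at the
#' window center (+/- jitter) on a random strand, and in `plant_fraction`
#' of windows plants a secondary site at exactly `gap` bp edge-to-edge in
#' the specified quadrant relative to the primary's orientation. Byte-
#' identical output for a fixed `rng_seed`.
#'
#' @param spec A [plant_spec()].
#' @return A list with `windows` (a [window_set()]), `truth` (a `data.frame`
#'   with `window_id`, `primary_pos`/`primary_strand` (1-based start and
#'   strand in the emitted window), `secondary_pos`/`secondary_strand`,
#'   `true_gap`, `quadrant`; `NA` where no secondary was planted), and the
#'   `spec`.
#' @export
generate <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  set.seed(spec$rng_seed)
  n <- spec$n_windows
  W <- spec$window_width
  wp <- spec$primary$width
  m <- .sample_background(spec$background, n, W)
  jit <- if (spec$primary_jitter > 0L)
    sample.int(2L * spec$primary_jitter + 1L, n, replace = TRUE) -
      spec$primary_jitter - 1L else integer(n)
  ps <- (W - wp) %/% 2L + 1L + jit
  psite <- .sample_sites(spec$primary, n, spec$consensus_only)
  for (jj in seq_len(wp)) m[cbind(seq_len(n), ps + jj - 1L)] <- psite[, jj]
  sec_pos <- rep(NA_integer_, n)
  sec_same <- rep(NA, n)
  planted <- logical(n)
  if (!is.null(spec$secondary) && spec$plant_fraction > 0) {
    ws <- spec$secondary$width
    n_plant <- round(spec$plant_fraction * n)
    planted[sample.int(n, n_plant)] <- TRUE
    idx <- which(planted)
    ss <- if (grepl("^upstream", spec$quadrant))
      ps[idx] - spec$gap - ws else ps[idx] + wp + spec$gap
    same <- grepl("same$", spec$quadrant)
    ssite <- .sample_sites(spec$secondary, length(idx), spec$consensus_only)
    if (!same) {
      # opposite strand: reverse-complement the site letters in place
      ssite <- matrix((5L - ssite)[, rev(seq_len(ws)), drop = FALSE],
                      nrow = length(idx))
    }
    for (jj in seq_len(ws)) m[cbind(idx, ss + jj - 1L)] <- ssite[, jj]
    sec_pos[idx] <- ss
    sec_same[idx] <- same
  }
  # flip each whole window to the minus strand with probability 1/2
  flip <- sample(c(FALSE, TRUE), n, replace = TRUE)
  if (any(flip))
    m[flip, ] <- matrix((5L - m[flip, , drop = FALSE])[
      , rev(seq_len(W)), drop = FALSE], nrow = sum(flip))
  p_pos <- ifelse(flip, W - (ps + wp - 1L) + 1L, ps)
  p_strand <- ifelse(flip, "-", "+")
  ws2 <- if (is.null(spec$secondary)) NA_integer_ else spec$secondary$width
  s_pos <- ifelse(planted,
                  ifelse(flip, W - (sec_pos + ws2 - 1L) + 1L, sec_pos),
                  NA_integer_)
  s_strand <- ifelse(planted,
                     ifelse(sec_same, p_strand,
                            ifelse(p_strand == "+", "-", "+")),
                     NA_character_)
  seqs <- vapply(seq_len(n), function(i)
    paste(.BASES_CHR[m[i, ]], collapse = ""), character(1))
  ids <- sprintf("w%05d", seq_len(n))
  truth <- data.frame(
    window_id = ids, primary_pos = p_pos, primary_strand = p_strand,
    secondary_pos = s_pos, secondary_strand = s_strand,
    true_gap = ifelse(planted, spec$gap, NA_integer_),
    quadrant = ifelse(planted, spec$quadrant, NA_character_),
    stringsAsFactors = FALSE)
  list(windows = window_set(ids, seqs), truth = truth, spec = spec)
}

#' Built-in composite-element motifs
#'
#' Convenience consensus-derived motif models for the validation scenarios:
#' AP-1 (`TGASTCA`), an IRF GAAA-core element (`AANTGAAA`), a GAS palindrome
#' (`TTCNNNGAA`, the STAT-dimer site), a CTCF-like core, and an ETS
#' GGAA-core motif.
#'
#' @return A [motif_db()] with motifs `AP1`, `IRF`, `GAS`, `CTCF`, `ETS`.
#' @export
preset_motifs <- function() {
  motif_db(list(
    motif_from_consensus("AP1", "TGASTCA"),
    motif_from_consensus("IRF", "AANTGAAA"),
    motif_from_consensus("GAS", "TTCNNNGAA"),
    motif_from_consensus("CTCF", "CCASYAGRKGGC"),
    motif_from_consensus("ETS", "CAGGAAGT")))
}

#' Preset planted datasets for the validated composite elements
#'
#' `generate_aice()` plants AP-1 (`TGASTCA`) with an IRF GAAA-core partner
#' at edge-to-edge gap 0 or 4 (half of the planted windows each);
#' `generate_gas_tetramer()` plants two GAS sites at a fixed gap (11 bp by
#' default, the STAT tetramer spacing); `generate_ctcf_ets()` plants a
#' CTCF-like site with an ETS partner at gap 8.
#'
#' @param n Number of windows.
#' @param seed Integer seed.
#' @param gap Edge-to-edge gap (tetramer preset).
#' @param plant_fraction Fraction of windows with the secondary site.
#' @return As [generate()]; the element `spec` is that of the last
#'   sub-dataset generated. The planted motif models are attached as
#'   `primary_motif` and `secondary_motif`.
#' @export
generate_aice <- function(n, seed = 1L, plant_fraction = 0.6) {
  db <- preset_motifs()
  half <- n %/% 2L
  d0 <- generate(plant_spec(half, primary = db[["AP1"]],
                            secondary = db[["IRF"]], gap = 0L,
                            plant_fraction = plant_fraction,
                            rng_seed = seed))
  d4 <- generate(plant_spec(n - half, primary = db[["AP1"]],
                            secondary = db[["IRF"]], gap = 4L,
                            plant_fraction = plant_fraction,
                            rng_seed = seed + 1L))
  .combine_datasets(d0, d4, db[["AP1"]], db[["IRF"]])
}

#' @rdname generate_aice
#' @export
generate_gas_tetramer <- function(n, gap = 11L, seed = 1L,
                                  plant_fraction = 0.6) {
  db <- preset_motifs()
  d <- generate(plant_spec(n, primary = db[["GAS"]],
                           secondary = db[["GAS"]], gap = gap,
                           plant_fraction = plant_fraction, rng_seed = seed))
  d$primary_motif <- db[["GAS"]]
  d$secondary_motif <- db[["GAS"]]
  d
}

#' @rdname generate_aice
#' @export
generate_ctcf_ets <- function(n, seed = 1L, plant_fraction = 0.6) {
  db <- preset_motifs()
  d <- generate(plant_spec(n, primary = db[["CTCF"]],
                           secondary = db[["ETS"]], gap = 8L,
                           plant_fraction = plant_fraction, rng_seed = seed))
  d$primary_motif <- db[["CTCF"]]
  d$secondary_motif <- db[["ETS"]]
  d
}

.combine_datasets <- function(a, b, primary_motif, secondary_motif) {
  b$windows$id <- paste0("b_", b$windows$id)
  b$truth$window_id <- paste0("b_", b$truth$window_id)
  windows <- rbind(a$windows, b$windows)
  class(windows) <- c("window_set", "data.frame")
  list(windows = windows, truth = rbind(a$truth, b$truth), spec = b$spec,
       primary_motif = primary_motif, secondary_motif = secondary_motif)
}

#' Write a truth table as TSV
#'
#' @param dataset Output of [generate()] or a preset generator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(dataset, path) {
  utils::write.table(dataset$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
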