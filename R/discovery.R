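# De novo primary-motif discovery: over-represented k-mer seeding followed
# by ZOOPS (zero-or-one occurrence per sequence) expectation-maximisation
# over both strands, ranking candidates by their log-likelihood-ratio score
# against a mononucleotide background.

#' Discovery configuration
#'
#' @param motif_width Motif width(s) to search; a vector triggers an outer
#'   loop over widths with selection by score. Must be >= 4.
#' @param n_seeds Number of over-represented k-mer seeds refined per width.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the change in total log-likelihood
#'   ratio (natural log units).
#' @param rng_seed Integer seed; the procedure is deterministic given the
#'   input, the seed is kept for reproducibility bookkeeping.
#' @return A list of class `discovery_config`.
#' @export
discovery_config <- function(motif_width = 8L, n_seeds = 5L, max_iter = 100L,
                             tol = 1e-4, rng_seed = 1L) {
  motif_width <- as.integer(motif_width)
  if (any(motif_width < 4L)) stop("motif_width must be >= 4")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  if (tol <= 0) stop("tol must be > 0")
  structure(list(motif_width = motif_width, n_seeds = as.integer(n_seeds),
                 max_iter = as.integer(max_iter), tol = tol,
                 rng_seed = as.integer(rng_seed)),
            class = "discovery_config")
}

# mononucleotide background of a window set (A,C,G,T frequencies)
estimate_background <- function(windows) {
  tab <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(windows$seq),
                                       collapse = TRUE)
  freq <- tab[c("A", "C", "G", "T")]
  if (sum(freq) == 0) stop("windows contain no A/C/G/T bases")
  as.numeric(freq / sum(freq))
}

.rc_string <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

#' Rank over-represented k-mer seeds
#'
#' Counts every k-mer across the windows (one strand; each k-mer is merged
#' with its reverse complement so both orientations are captured), computes
#' its expected count under the windows' mononucleotide composition, and
#' ranks by `log2((observed + 0.5) / (expected + 0.5))`.
#'
#' @param windows A [window_set()].
#' @param k K-mer length.
#' @param n_seeds Number of top seeds to return.
#' @return A `data.frame` with columns `kmer` (canonical orientation),
#'   `count`, `expected`, `log2_ratio`, ranked by decreasing ratio.
#' @export
seed_kmers <- function(windows, k, n_seeds = 5L) {
  if (!nrow(windows)) stop("no windows supplied")
  k <- as.integer(k)
  if (any(nchar(windows$seq) < k))
    stop("k (", k, ") exceeds the width of at least one window")
  kmers <- unlist(lapply(windows$seq, function(s) {
    L <- nchar(s)
    substring(s, 1:(L - k + 1L), k:L)
  }), use.names = FALSE)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  if (!length(kmers))
    stop("no A/C/G/T-only k-mers found (all-N input?)")
  bg <- estimate_background(windows)
  names(bg) <- c("A", "C", "G", "T")
  counts <- table(kmers)
  # merge each k-mer with its reverse complement under a canonical key
  nm <- names(counts)
  rc <- .rc_string(nm)
  canon <- ifelse(nm <= rc, nm, rc)
  obs <- tapply(as.integer(counts), canon, sum)
  keys <- names(obs)
  kmer_prob <- function(s) prod(bg[strsplit(s, "")[[1]]])
  p <- vapply(keys, kmer_prob, numeric(1)) +
    ifelse(keys == .rc_string(keys), 0,
           vapply(.rc_string(keys), kmer_prob, numeric(1)))
  expected <- length(kmers) * p
  ratio <- log2((as.numeric(obs) + 0.5) / (expected + 0.5))
  ord <- order(-ratio, keys)
  out <- data.frame(kmer = keys[ord],
                    count = as.integer(obs[ord]),
                    expected = expected[ord],
                    log2_ratio = ratio[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  utils::head(out, n_seeds)
}

# log(sum(exp(...))) along rows of a matrix plus a per-row scalar column
.row_logsumexp <- function(mat, extra) {
  m <- pmax(apply(mat, 1L, max), extra)
  m + log(rowSums(exp(mat - m)) + exp(extra - m))
}

#' Refine a seed k-mer into a motif by ZOOPS EM
#'
#' The model: each window independently carries a motif site with
#' probability `gamma` (the site prior); given a site, its position and
#' strand are uniform over all placements; bases outside the site (and whole
#' windows without one) follow the mononucleotide background. The E-step
#' computes posterior placement probabilities (including the no-site state),
#' the M-step re-estimates the position frequency matrix and `gamma`;
#' iteration stops when the total log-likelihood-ratio changes by less than
#' `tol` or after `max_iter` iterations (then the best-so-far model is
#' returned with `converged = FALSE`, not an error).
#'
#' @param seed A plain A/C/G/T k-mer to initialise the PFM.
#' @param windows A [window_set()].
#' @param config A [discovery_config()] (its `motif_width` is ignored; the
#'   width is the seed length).
#' @return A list of class `motif_candidate`: `motif` ([motif_model()]),
#'   `score` (final total log-likelihood ratio vs the background-only model,
#'   natural log), `n_sites` (windows with posterior site probability >
#'   0.5), `gamma`, `converged`, `loglik_trace`.
#' @export
em_refine <- function(seed, windows, config = discovery_config()) {
  if (grepl("[^ACGT]", seed)) stop("seed must be a plain A/C/G/T k-mer")
  w <- nchar(seed)
  if (!nrow(windows)) stop("no windows supplied")
  bg <- estimate_background(windows)
  # group windows by length; keep per-group code matrices
  lens <- nchar(windows$seq)
  if (any(lens < w)) {
    windows <- windows[lens >= w, , drop = FALSE]
    lens <- lens[lens >= w]
    if (!nrow(windows)) stop("every window is shorter than the seed")
  }
  groups <- lapply(split(seq_len(nrow(windows)), lens),
                   function(idx) seq_code_matrix(windows$seq[idx]))
  # initial PFM: seed base 0.7, others 0.1
  seed_codes <- .CODE_MAP[utf8ToInt(seed)]
  theta <- matrix(0.1, w, 4L)
  theta[cbind(seq_len(w), seed_codes)] <- 0.7
  gamma <- 0.5
  pseudo <- 1e-8
  trace <- numeric(0)
  prev_ll <- -Inf
  converged <- FALSE
  for (iter in seq_len(config$max_iter)) {
    bgmat <- matrix(bg, w, 4L, byrow = TRUE)
    llr <- log(theta / bgmat)
    # minus-strand placement: position j of the motif emits the complement
    # of the observed base, but the background term stays that of the
    # observed base itself
    llr_rc <- log(theta[rev(seq_len(w)), c(4L, 3L, 2L, 1L),
                        drop = FALSE] / bgmat)
    counts <- matrix(0, w, 4L)
    gamma_num <- 0
    n_win <- 0
    ll <- 0
    site_post <- numeric(0)
    for (codes in groups) {
      S <- ncol(codes) - w + 1L
      m <- 2L * S
      lp <- .scan_strand(codes, llr)   # n x S, natural-log LR per placement
      lm <- .scan_strand(codes, llr_rc)
      a <- cbind(lp, lm) + log(gamma / m)
      a0 <- log(1 - gamma)
      logD <- .row_logsumexp(a, a0)
      ll <- ll + sum(logD)
      r <- exp(a - logD)               # n x 2S posterior placements
      r0 <- exp(a0 - logD)
      site_post <- c(site_post, 1 - r0)
      gamma_num <- gamma_num + sum(1 - r0)
      n_win <- n_win + nrow(codes)
      rp <- r[, seq_len(S), drop = FALSE]
      rm <- r[, S + seq_len(S), drop = FALSE]
      for (j in seq_len(w)) {
        block <- codes[, j:(j + S - 1L), drop = FALSE]
        block_m <- codes[, (w - j + 1L):(w - j + S), drop = FALSE]
        for (b in 1:4) {
          counts[j, b] <- counts[j, b] + sum(rp[block == b]) +
            sum(rm[block_m == (5L - b)])
        }
      }
    }
    trace <- c(trace, ll)
    if (is.finite(prev_ll) && abs(ll - prev_ll) < config$tol) {
      converged <- TRUE
      break
    }
    prev_ll <- ll
    gamma <- min(max(gamma_num / n_win, 1e-6), 1 - 1e-6)
    counts <- counts + pseudo * matrix(bg, w, 4L, byrow = TRUE)
    theta <- counts / rowSums(counts)
  }
  motif <- motif_model(paste0("denovo_", seed), theta, background = bg)
  structure(list(motif = motif, score = trace[length(trace)],
                 n_sites = sum(site_post > 0.5), gamma = gamma,
                 converged = converged, loglik_trace = trace),
            class = "motif_candidate")
}

#' @export
print.motif_candidate <- function(x, ...) {
  cat(sprintf("<motif_candidate> %s  score %.2f  n_sites %d  %s\n",
              motif_consensus(x$motif), x$score, x$n_sites,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Discover the primary motif of a window set
#'
#' Refines each of the top over-represented k-mer seeds by ZOOPS EM (for
#' every width in `config$motif_width`), removes redundant candidates
#' (pairwise [motif_similarity()] >= 0.9, keeping the higher-scoring one),
#' and ranks by score. The first candidate is the primary motif.
#'
#' @param windows A [window_set()].
#' @param config A [discovery_config()].
#' @return An object of class `spice_discovery`: list with `candidates`
#'   (list of `motif_candidate`, ranked) and `primary` (the top candidate's
#'   [motif_model()]).
#' @export
discover_primary <- function(windows, config = discovery_config()) {
  if (!nrow(windows)) stop("no windows supplied")
  set.seed(config$rng_seed)
  cands <- list()
  for (w in config$motif_width) {
    seeds <- seed_kmers(windows, w, config$n_seeds)
    cands <- c(cands, lapply(seeds$kmer, em_refine, windows = windows,
                             config = config))
  }
  cands <- cands[order(-vapply(cands, `[[`, numeric(1), "score"))]
  kept <- list()
  for (cand in cands) {
    dup <- any(vapply(kept, function(kc)
      motif_similarity(kc$motif, cand$motif,
                       min_overlap = min(5L, kc$motif$width,
                                         cand$motif$width)) >= 0.9,
      logical(1)))
    if (!dup) kept[[length(kept) + 1L]] <- cand
  }
  structure(list(candidates = kept, primary = kept[[1L]]$motif),
            class = "spice_discovery")
}

#' @export
print.spice_discovery <- function(x, ...) {
  cat("<spice_discovery> ", length(x$candidates), " candidate motif(s)\n",
      sep = "")
  for (cand in x$candidates) print(cand)
  invisible(x)
}
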