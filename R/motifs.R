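# Motif models and motif database I/O.
#
# Conventions used throughout the package:
#   * alphabet order is A, C, G, T; the complement permutation is T, G, C, A;
#   * a PFM has one row per motif position and one column per base, rows
#     summing to 1;
#   * the PWM is the log2-odds of the pseudocount-smoothed PFM against the
#     background base frequencies.

.ALPHABET <- c("A", "C", "G", "T")
.COMP_PERM <- c(4L, 3L, 2L, 1L)

#' Construct a motif model
#'
#' A motif model couples a position frequency matrix (PFM) with its log-odds
#' scoring form (PWM) against a background base composition. The PWM entry for
#' base `b` at position `i` is `log2(p'[i,b] / background[b])` where `p'` is
#' the pseudocount-smoothed probability `(p + c * background) / (1 + c)`.
#' Smoothing guarantees a finite PWM even for PFM entries of exactly zero.
#'
#' @param name Motif identifier.
#' @param pfm Numeric matrix, one row per position, four columns in A,C,G,T
#'   order. Rows are renormalized to sum to 1; non-negative counts (e.g. a
#'   JASPAR PCM) are therefore accepted directly.
#' @param background Length-4 vector of background base frequencies
#'   (A,C,G,T); renormalized; every entry must be positive.
#' @param pseudocount Smoothing fraction `c` in `(p + c*bg)/(1 + c)`.
#' @return An object of class `motif_model` with elements `name`, `width`,
#'   `pfm`, `pwm`, `background`.
#' @examples
#' m <- motif_model("ap1", consensus_pfm("TGASTCA"))
#' m
#' @export
motif_model <- function(name, pfm, background = rep(0.25, 4),
                        pseudocount = 0.01) {
  pfm <- as.matrix(pfm)
  if (ncol(pfm) != 4L)
    stop("pfm must have 4 columns (A,C,G,T); got ", ncol(pfm))
  if (nrow(pfm) < 1L)
    stop("pfm must have at least one row")
  if (any(pfm < 0) || any(!is.finite(pfm)))
    stop("pfm entries must be finite and non-negative")
  rs <- rowSums(pfm)
  if (any(rs <= 0))
    stop("motif '", name, "': a pfm row sums to zero")
  pfm <- pfm / rs
  dimnames(pfm) <- list(NULL, .ALPHABET)
  background <- as.numeric(background)
  if (length(background) != 4L || any(background <= 0))
    stop("background must be 4 positive frequencies")
  background <- background / sum(background)
  bgmat <- matrix(background, nrow(pfm), 4L, byrow = TRUE)
  smoothed <- (pfm + pseudocount * bgmat) / (1 + pseudocount)
  pwm <- log2(smoothed / bgmat)
  dimnames(pwm) <- dimnames(pfm)
  structure(
    list(name = as.character(name), width = nrow(pfm), pfm = pfm, pwm = pwm,
         background = background, pseudocount = pseudocount),
    class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("<motif_model> ", x$name, "  width ", x$width,
      "  consensus ", motif_consensus(x), "\n", sep = "")
  invisible(x)
}

#' Reverse complement of a motif model
#'
#' Column `i` of the result is the complement-permuted column `width - i + 1`
#' of the input, for both the PFM and the PWM; the background is complemented
#' as well. Applying the operation twice returns the original model.
#'
#' @param motif A `motif_model`.
#' @return A `motif_model` on the opposite strand.
#' @export
motif_rc <- function(motif) {
  stopifnot(inherits(motif, "motif_model"))
  idx <- rev(seq_len(motif$width))
  out <- motif
  out$pfm <- motif$pfm[idx, .COMP_PERM, drop = FALSE]
  out$pwm <- motif$pwm[idx, .COMP_PERM, drop = FALSE]
  dimnames(out$pfm) <- dimnames(out$pwm) <- list(NULL, .ALPHABET)
  out$background <- motif$background[.COMP_PERM]
  out
}

#' Consensus string of a motif (majority base per position)
#'
#' @param motif A `motif_model`.
#' @return Character scalar.
#' @export
motif_consensus <- function(motif) {
  paste(.ALPHABET[max.col(motif$pfm, ties.method = "first")], collapse = "")
}

#' Maximum achievable log-odds score of a motif
#'
#' Sum over positions of the best-base PWM entry; the score of the ideal site.
#'
#' @param motif A `motif_model`.
#' @return Numeric scalar.
#' @export
motif_max_score <- function(motif) sum(apply(motif$pwm, 1L, max))

# IUPAC degeneracy codes -> allowed bases (indices into A,C,G,T)
.IUPAC <- list(
  A = 1L, C = 2L, G = 3L, T = 4L,
  R = c(1L, 3L), Y = c(2L, 4L), S = c(2L, 3L), W = c(1L, 4L),
  K = c(3L, 4L), M = c(1L, 2L),
  B = c(2L, 3L, 4L), D = c(1L, 3L, 4L), H = c(1L, 2L, 4L), V = c(1L, 2L, 3L),
  N = 1:4)

#' Build a PFM from an IUPAC consensus string
#'
#' Bases allowed by each consensus letter jointly carry roughly `prob` of
#' the column mass; the remainder goes to the disallowed bases. Column
#' probabilities are deliberately made generically distinct — the allowed
#' mass varies slightly with the position and both the allowed and the
#' disallowed bases receive unequal shares — so that, as with real database
#' PFMs, distinct site sequences essentially never produce exactly tied
#' log-odds scores (exact ties would otherwise be resolved by the
#' deterministic placement tie-break and bias spacing counts toward small
#' gaps). Fully degenerate positions (`N`) are near-uniform with the same
#' mild skew.
#'
#' @param consensus IUPAC DNA string.
#' @param prob Approximate total probability of the allowed bases at each
#'   position.
#' @return A numeric PFM matrix suitable for [motif_model()].
#' @export
consensus_pfm <- function(consensus, prob = 0.97) {
  letters <- strsplit(toupper(consensus), "")[[1]]
  bad <- setdiff(letters, names(.IUPAC))
  if (length(bad))
    stop("unsupported consensus letter(s): ", paste(bad, collapse = ", "))
  t(vapply(seq_along(letters), function(j) {
    allowed <- .IUPAC[[letters[j]]]
    na <- length(allowed)
    if (na == 4L) {
      p <- c(0.28, 0.26, 0.24, 0.22)
    } else {
      # position-dependent consensus strength; unequal within-group shares
      q <- prob - 0.0025 * (j - 1L)
      wa <- seq(1.06, 0.94, length.out = na)
      wd <- seq(0.85, 1.15, length.out = 4L - na)
      p <- numeric(4L)
      p[allowed] <- q * wa / sum(wa)
      p[-allowed] <- (1 - q) * wd / sum(wd)
    }
    p / sum(p)
  }, numeric(4L)))
}

#' @rdname consensus_pfm
#' @param name Motif identifier.
#' @param background,pseudocount Passed to [motif_model()].
#' @export
motif_from_consensus <- function(name, consensus, prob = 0.97,
                                 background = rep(0.25, 4),
                                 pseudocount = 0.01) {
  motif_model(name, consensus_pfm(consensus, prob), background, pseudocount)
}

#' Motif database
#'
#' An ordered collection of [motif_model()] objects with a shared source
#' background. Motif names must be unique.
#'
#' @param motifs List of `motif_model` objects.
#' @param background Length-4 source background.
#' @return An object of class `motif_db`; supports `length()`, `names()`,
#'   `[[` (by index or name) and `[` (subset, returns a `motif_db`).
#' @export
motif_db <- function(motifs, background = rep(0.25, 4)) {
  stopifnot(is.list(motifs), length(motifs) >= 1L,
            all(vapply(motifs, inherits, logical(1), "motif_model")))
  nms <- vapply(motifs, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate motif name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(motifs) <- nms
  structure(list(motifs = motifs, background = background / sum(background)),
            class = "motif_db")
}

#' @export
length.motif_db <- function(x) length(x$motifs)

#' @export
names.motif_db <- function(x) names(x$motifs)

#' @export
`[[.motif_db` <- function(x, i) x$motifs[[i]]

#' @export
`[.motif_db` <- function(x, i) motif_db(x$motifs[i], x$background)

#' @export
print.motif_db <- function(x, ...) {
  cat("<motif_db> ", length(x), " motifs; widths ",
      paste(range(vapply(x$motifs, `[[`, integer(1), "width")),
            collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' Read motifs in MEME minimal format
#'
#' Parses a MEME minimal motif file (version line, optional `ALPHABET` and
#' `Background letter frequencies` lines, `MOTIF` blocks with
#' `letter-probability matrix` headers). Matrix rows are renormalized; the
#' PWM of every motif is computed against the file's background line when
#' present, otherwise against a uniform background.
#'
#' @param path File path.
#' @param pseudocount Smoothing fraction, see [motif_model()].
#' @return A [motif_db()].
#' @export
read_meme_motifs <- function(path, pseudocount = 0.01) {
  lines <- readLines(path, warn = FALSE)
  alpha_ln <- grep("^ALPHABET", lines, value = TRUE)
  if (length(alpha_ln)) {
    alpha <- gsub("ALPHABET\\s*=?\\s*", "", alpha_ln[1])
    if (!grepl("^ACGT$", trimws(alpha)))
      stop("unsupported alphabet '", trimws(alpha), "': only ACGT DNA motifs")
  }
  background <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    # frequencies may continue over several lines until the next blank/MOTIF
    j <- bg_at[1] + 1L
    toks <- character(0)
    while (j <= length(lines) && !grepl("^\\s*(MOTIF|$)", lines[j])) {
      toks <- c(toks, strsplit(trimws(lines[j]), "\\s+")[[1]])
      j <- j + 1L
    }
    if (length(toks) >= 8) {
      freq <- as.numeric(toks[seq(2, 8, by = 2)])
      base <- toks[seq(1, 7, by = 2)]
      if (!anyNA(freq) && identical(toupper(base), .ALPHABET))
        background <- freq
    }
  }
  motif_at <- grep("^MOTIF\\s", lines)
  if (!length(motif_at))
    stop("no MOTIF blocks found in ", path)
  motifs <- vector("list", length(motif_at))
  bounds <- c(motif_at, length(lines) + 1L)
  for (k in seq_along(motif_at)) {
    block <- lines[motif_at[k]:(bounds[k + 1L] - 1L)]
    name <- strsplit(trimws(block[1]), "\\s+")[[1]][2]
    if (is.na(name)) stop("MOTIF line without a name at line ", motif_at[k])
    hdr <- grep("letter-probability matrix", block)
    if (!length(hdr))
      stop("motif '", name, "': no letter-probability matrix header")
    rows <- list()
    for (j in (hdr[1] + 1L):length(block)) {
      ln <- trimws(block[j])
      if (ln == "" || grepl("^(URL|MOTIF)", ln)) break
      vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
      if (length(vals) != 4L || anyNA(vals))
        stop("motif '", name, "': malformed matrix row at line ",
             motif_at[k] + hdr[1] + length(rows),
             " (expected 4 numeric columns)")
      rows[[length(rows) + 1L]] <- vals
    }
    if (!length(rows)) stop("motif '", name, "': empty matrix")
    motifs[[k]] <- motif_model(name, do.call(rbind, rows),
                               background, pseudocount)
  }
  motif_db(motifs, background)
}

#' Write a motif database in MEME minimal format
#'
#' @param db A [motif_db()].
#' @param path Output file path.
#' @param digits Significant digits for probabilities.
#' @return `path`, invisibly.
#' @export
write_meme_motifs <- function(db, path, digits = 12) {
  stopifnot(inherits(db, "motif_db"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.*g", .ALPHABET, digits, db$background),
                     collapse = " "),
               ""), con)
  for (m in db$motifs) {
    writeLines(sprintf("MOTIF %s", m$name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", m$width),
      con)
    writeLines(apply(m$pfm, 1L, function(r)
      paste(sprintf("%.*f", digits, r), collapse = "  ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs in JASPAR PFM format
#'
#' Accepts the four-row JASPAR count format, either bracketed
#' (`A [ 1 2 3 ]`) or bare rows of numbers, one `>name` header per motif.
#' Counts are normalized to probabilities (zeros allowed; smoothing happens
#' in [motif_model()]).
#'
#' @inheritParams read_meme_motifs
#' @param background Background frequencies for PWM construction.
#' @return A [motif_db()].
#' @export
read_jaspar_motifs <- function(path, pseudocount = 0.01,
                               background = rep(0.25, 4)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  hdr_at <- grep("^>", lines)
  if (!length(hdr_at)) stop("no '>' motif headers found in ", path)
  bounds <- c(hdr_at, length(lines) + 1L)
  motifs <- vector("list", length(hdr_at))
  for (k in seq_along(hdr_at)) {
    name <- strsplit(sub("^>\\s*", "", lines[hdr_at[k]]), "\\s+")[[1]][1]
    body <- lines[(hdr_at[k] + 1L):(bounds[k + 1L] - 1L)]
    if (length(body) != 4L)
      stop("motif '", name, "': expected 4 count rows, got ", length(body))
    rows <- lapply(body, function(ln) {
      ln <- gsub("^[ACGTacgt]\\s*\\[?|\\]\\s*$", "", trimws(ln))
      vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      if (anyNA(vals)) stop("motif '", name, "': malformed count row")
      vals
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("motif '", name, "': ragged count rows")
    counts <- do.call(cbind, rows)   # width x 4, rows were A,C,G,T
    motifs[[k]] <- motif_model(name, counts, background, pseudocount)
  }
  motif_db(motifs, background)
}

#' Similarity between two motifs
#'
#' Maximum Pearson correlation between the flattened aligned PFM sub-matrices
#' over all ungapped offsets with at least `min_overlap` aligned columns,
#' with `b` considered in both orientations. Symmetric in its arguments and
#' invariant to reverse-complementing either one.
#'
#' @param a,b `motif_model` objects.
#' @param min_overlap Minimum number of aligned motif positions.
#' @return Similarity score in `[-1, 1]`.
#' @export
motif_similarity <- function(a, b, min_overlap = 5L) {
  stopifnot(inherits(a, "motif_model"), inherits(b, "motif_model"))
  min_overlap <- as.integer(min_overlap)
  if (min_overlap < 1L) stop("min_overlap must be >= 1")
  if (min_overlap > min(a$width, b$width))
    stop("min_overlap (", min_overlap, ") exceeds the smaller motif width (",
         min(a$width, b$width), ")")
  best <- -Inf
  for (bb in list(b, motif_rc(b))) {
    for (off in seq(-(bb$width - min_overlap), a$width - min_overlap)) {
      ai <- max(1L, 1L + off):min(a$width, bb$width + off)
      bi <- ai - off
      if (length(ai) < min_overlap) next
      va <- as.vector(a$pfm[ai, , drop = FALSE])
      vb <- as.vector(bb$pfm[bi, , drop = FALSE])
      if (stats::sd(va) == 0 || stats::sd(vb) == 0) next
      best <- max(best, stats::cor(va, vb))
    }
  }
  if (!is.finite(best)) 0 else best
}
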