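# ChIP-Seq peak I/O, peak ranking, summit-centered sequence windows, and
# peak co-localization counting.
#
# Genomic coordinates follow the BED convention: 0-based, half-open
# [start, end). Positions inside R string objects (window sequences, match
# positions) are 1-based, as is idiomatic in R; the boundary is the file
# format layer.

#' Read an ENCODE narrowPeak or BED6 peak file
#'
#' narrowPeak is BED6+4; column 8 is -log10(p-value) and column 10 the peak
#' summit offset from `start`. Plain BED6 input is accepted, in which case
#' `summit_offset` is set to -1 (the summit falls back to the interval
#' midpoint downstream) and the score column stands in for the missing
#' -log10(p) ranking key. Lines starting with `#`, `track` or `browser` are
#' skipped.
#'
#' @param path File path.
#' @return A `data.frame` of class `peak_set` with columns `chrom`, `start`,
#'   `end` (0-based half-open), `name`, `score`, `strand`, `signal`,
#'   `neglog10p`, `qvalue`, `summit_offset`.
#' @export
read_narrowpeak <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & trimws(lines) != ""
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = numeric(), strand = character(),
                      signal = numeric(), neglog10p = numeric(),
                      qvalue = numeric(), summit_offset = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("peak_set", "data.frame")
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 6L))
    stop("line ", lineno[which(ncol < 6L)[1]],
         ": expected at least 6 tab-separated columns, got ",
         ncol[which(ncol < 6L)[1]])
  get <- function(i, default = NA_character_)
    vapply(fields, function(f) if (length(f) >= i) f[i] else default,
           character(1))
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("line ", lineno[bad[1]], ": non-integer coordinates")
  if (any(start >= end))
    stop("line ", lineno[which(start >= end)[1]], ": start >= end")
  narrow <- ncol >= 10L
  out <- data.frame(
    chrom = get(1), start = start, end = end,
    name = get(4), score = suppressWarnings(as.numeric(get(5))),
    strand = get(6),
    signal = suppressWarnings(as.numeric(ifelse(narrow, get(7), NA))),
    neglog10p = suppressWarnings(as.numeric(ifelse(narrow, get(8), get(5)))),
    qvalue = suppressWarnings(as.numeric(ifelse(narrow, get(9), NA))),
    summit_offset = suppressWarnings(
      as.integer(ifelse(narrow, get(10), "-1"))),
    stringsAsFactors = FALSE)
  out$summit_offset[is.na(out$summit_offset)] <- -1L
  class(out) <- c("peak_set", "data.frame")
  out
}

# Summit position (0-based) of each peak: start + offset, or the interval
# midpoint when no offset is recorded.
peak_summits <- function(peaks) {
  ifelse(peaks$summit_offset >= 0L,
         peaks$start + peaks$summit_offset,
         (peaks$start + peaks$end) %/% 2L)
}

#' Select the most significant peaks
#'
#' Returns the `n` peaks with the largest `neglog10p`, ties broken by
#' `(chrom, start)` so the selection is deterministic under input
#' permutation. Fewer than `n` peaks are returned unchanged (re-sorted).
#'
#' @param peaks A `peak_set`.
#' @param n Number of peaks to keep.
#' @return A `peak_set` of at most `n` rows.
#' @export
select_top_peaks <- function(peaks, n) {
  stopifnot(n >= 1)
  ord <- order(-peaks$neglog10p, peaks$chrom, peaks$start)
  out <- peaks[ord[seq_len(min(n, nrow(peaks)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Resolve a genome argument to a named DNAStringSet: accepts a DNAStringSet,
# a named character vector of sequences, or a FASTA file path.
.as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    return(Biostrings::readDNAStringSet(genome))
  if (is.character(genome) && !is.null(names(genome)))
    return(Biostrings::DNAStringSet(genome))
  stop("genome must be a DNAStringSet, a named character vector, ",
       "or a FASTA file path")
}

#' Extract fixed-width sequence windows centered on peak summits
#'
#' Each window spans `[summit - width/2, summit + width/2)` in 0-based
#' genomic coordinates. Windows truncated by a chromosome end are discarded
#' so that every returned window has exactly `width` bases. Sequences are
#' upper-cased.
#'
#' @param peaks A `peak_set`.
#' @param genome A `DNAStringSet`, named character vector, or FASTA path.
#' @param width Even window width in bp (500 by default, matching
#'   summit-centered composite-element scans).
#' @return A `data.frame` of class `window_set` with columns `id`, `seq`,
#'   `chrom`, `start`, `end` (0-based half-open provenance).
#' @export
extract_windows <- function(peaks, genome, width = 500L) {
  width <- as.integer(width)
  if (width %% 2L != 0L) stop("width must be even, got ", width)
  genome <- .as_genome(genome)
  # Names in FASTA headers may carry descriptions; match on the first token.
  names(genome) <- vapply(strsplit(names(genome), "\\s+"), `[[`, character(1), 1)
  missing_chr <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing_chr))
    stop("chromosome(s) absent from genome: ",
         paste(missing_chr, collapse = ", "))
  if (!nrow(peaks)) return(window_set(character(), character()))
  summit <- peak_summits(peaks)
  half <- width %/% 2L
  gstart <- summit - half            # 0-based
  gend <- summit + half
  chrlen <- Biostrings::width(genome)[match(peaks$chrom, names(genome))]
  keep <- gstart >= 0L & gend <= chrlen
  if (!any(keep)) return(window_set(character(), character()))
  idx <- which(keep)
  ids <- ifelse(!is.na(peaks$name[idx]) & peaks$name[idx] != "." &
                  peaks$name[idx] != "",
                peaks$name[idx], paste0("peak_", idx))
  seqs <- as.character(Biostrings::subseq(
    genome[peaks$chrom[idx]], start = gstart[idx] + 1L, end = gend[idx]))
  window_set(ids, toupper(seqs), chrom = peaks$chrom[idx],
             start = gstart[idx], end = gend[idx])
}

#' Construct a window set
#'
#' @param id Window identifiers.
#' @param seq DNA sequences (A/C/G/T/N).
#' @param chrom,start,end Optional genomic provenance (0-based half-open).
#' @return A `data.frame` of class `window_set`.
#' @export
window_set <- function(id, seq, chrom = NA_character_, start = NA_integer_,
                       end = NA_integer_) {
  out <- data.frame(id = as.character(id), seq = toupper(as.character(seq)),
                    chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  class(out) <- c("window_set", "data.frame")
  out
}

#' @export
print.window_set <- function(x, ...) {
  cat("<window_set> ", nrow(x), " windows",
      if (nrow(x)) paste0("; widths ",
                          paste(range(nchar(x$seq)), collapse = "-")),
      "\n", sep = "")
  invisible(x)
}

#' Write windows as FASTA
#'
#' Headers have the form `id|chrom:start-end` (or bare `id` when no
#' provenance is recorded).
#'
#' @param windows A `window_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows_fasta <- function(windows, path) {
  hdr <- ifelse(is.na(windows$chrom), windows$id,
                sprintf("%s|%s:%d-%d", windows$id, windows$chrom,
                        windows$start, windows$end))
  x <- Biostrings::DNAStringSet(windows$seq)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read windows from FASTA
#'
#' Inverse of [write_windows_fasta()]; `id|chrom:start-end` headers are
#' decomposed back into provenance columns.
#'
#' @param path FASTA file path.
#' @return A `window_set`.
#' @export
read_windows_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- names(x)
  has_loc <- grepl("^[^|]+\\|[^:]+:\\d+-\\d+$", hdr)
  id <- ifelse(has_loc, sub("\\|.*$", "", hdr), hdr)
  chrom <- ifelse(has_loc, sub("^[^|]+\\|([^:]+):.*$", "\\1", hdr),
                  NA_character_)
  start <- ifelse(has_loc,
                  as.integer(sub("^.*:(\\d+)-\\d+$", "\\1", hdr)), NA)
  end <- ifelse(has_loc, as.integer(sub("^.*-(\\d+)$", "\\1", hdr)), NA)
  window_set(id, as.character(x), chrom, start, end)
}

#' Count peak co-localization
#'
#' A peak in `a` counts as co-localized when any peak in `b` shares at least
#' one base with it (non-empty intersection of the half-open intervals;
#' intervals that merely touch do not overlap).
#'
#' @param a,b `peak_set` objects (or data.frames with `chrom`, `start`,
#'   `end`).
#' @return A list with `n_total` (peaks in `a`), `n_overlap` (peaks of `a`
#'   overlapping `b`), and `fraction`.
#' @export
peak_overlap <- function(a, b) {
  if (!nrow(a)) stop("peak set 'a' is empty; overlap fraction is undefined")
  gr <- function(p) GenomicRanges::GRanges(
    p$chrom, IRanges::IRanges(start = p$start + 1L, end = p$end))
  hits <- if (nrow(b))
    GenomicRanges::countOverlaps(gr(a), gr(b), minoverlap = 1L) else
    integer(nrow(a))
  n_ov <- sum(hits > 0L)
  list(n_total = nrow(a), n_overlap = n_ov, fraction = n_ov / nrow(a))
}
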