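# Vectorized PWM scanning over sets of equal-length windows.
#
# Sequences are encoded as integer codes 1..5 (A,C,G,T,other); placements
# covering a non-ACGT base score an effectively -infinite value and can never
# be the best site. Windows of equal length are scored as one code matrix:
# for each motif column j the per-start score accumulates
# lut[code[, start + j - 1], j], which keeps the inner loop at `width`
# matrix operations regardless of the number of windows.

.CODE_MAP <- local({
  m <- rep(5L, 127L)
  m[utf8ToInt("A")] <- 1L; m[utf8ToInt("a")] <- 1L
  m[utf8ToInt("C")] <- 2L; m[utf8ToInt("c")] <- 2L
  m[utf8ToInt("G")] <- 3L; m[utf8ToInt("g")] <- 3L
  m[utf8ToInt("T")] <- 4L; m[utf8ToInt("t")] <- 4L
  m
})

.NEG <- -1e9  # sentinel for illegal placements (overlap with N etc.)

# character vector of equal-length sequences -> n x L integer code matrix
seq_code_matrix <- function(seqs) {
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("internal: sequences of unequal length in one code matrix")
  matrix(.CODE_MAP[utf8ToInt(paste(seqs, collapse = ""))],
         nrow = length(seqs), ncol = L, byrow = TRUE)
}

# reverse complement at the code level (5 = N maps to itself)
.rc_codes <- function(m) {
  comp <- c(4L, 3L, 2L, 1L, 5L)
  matrix(comp[m[, rev(seq_len(ncol(m))), drop = FALSE]], nrow = nrow(m))
}

# 5 x width lookup table from a width x 4 score matrix
.pwm_lut <- function(pwm) rbind(t(pwm), rep(.NEG, nrow(pwm)))

# Score every start position of every window on one strand.
# codes: n x L matrix; scores: n x (L - w + 1) matrix.
.scan_strand <- function(codes, pwm) {
  w <- nrow(pwm)
  L <- ncol(codes)
  S <- L - w + 1L
  if (S < 1L) return(matrix(numeric(0), nrow(codes), 0L))
  lut <- .pwm_lut(pwm)
  acc <- matrix(0, nrow(codes), S)
  for (j in seq_len(w)) {
    block <- codes[, j:(j + S - 1L), drop = FALSE]
    acc <- acc + matrix(lut[(j - 1L) * 5L + block], nrow(codes))
  }
  # any placement touching a non-ACGT base is far below any real score
  acc[acc < .NEG / 2] <- -Inf
  acc
}

# Scores on both strands. The minus-strand score at start s is the score of
# a site lying on the reverse strand and covering [s, s + w), i.e. the
# forward scan with the reverse-complemented PWM.
scan_pwm_codes <- function(codes, motif) {
  list(plus = .scan_strand(codes, motif$pwm),
       minus = .scan_strand(codes, motif_rc(motif)$pwm))
}

# Best match per window over both strands; ties go to the leftmost position,
# then to the plus strand. Returns data.frame(position, strand, score) with
# NA rows where no placement exists.
best_match_codes <- function(codes, motif) {
  sc <- scan_pwm_codes(codes, motif)
  n <- nrow(codes)
  if (ncol(sc$plus) == 0L)
    return(data.frame(position = rep(NA_integer_, n),
                      strand = rep(NA_character_, n),
                      score = rep(NA_real_, n)))
  # compare on scores rounded to 9 decimals: sites with identical letters on
  # opposite strands sum the same PWM entries in a different order and can
  # differ by an ulp, which would defeat the deterministic tie-break
  rp <- round(sc$plus, 9)
  rm <- round(sc$minus, 9)
  pp <- max.col(rp, ties.method = "first")
  pm <- max.col(rm, ties.method = "first")
  sp <- sc$plus[cbind(seq_len(n), pp)]
  sm <- sc$minus[cbind(seq_len(n), pm)]
  take_minus <- rm[cbind(seq_len(n), pm)] > rp[cbind(seq_len(n), pp)] |
    (rm[cbind(seq_len(n), pm)] == rp[cbind(seq_len(n), pp)] & pm < pp)
  data.frame(position = ifelse(take_minus, pm, pp),
             strand = ifelse(take_minus, "-", "+"),
             score = pmax(sp, sm))
}
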