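# Independent oracles and fixture builders. These deliberately avoid the
# package's own code paths (explicit loops, naive arithmetic) so that
# implementation and expectation stay decoupled.

# random motif with generic (tie-free) columns
rand_motif <- function(w, seed, name = paste0("rand", seed)) {
  set.seed(seed)
  pfm <- matrix(stats::runif(4 * w, 0.05, 1), w, 4)
  motif_model(name, pfm / rowSums(pfm))
}

# reverse complement of a DNA string, written independently
rc_str <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# exact upper binomial tail P[X >= k] by log-space term summation
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

# brute-force motif similarity: every offset, both orientations, plain loops
oracle_similarity <- function(a, b, min_overlap) {
  rc_pfm <- function(p) {
    w <- nrow(p)
    out <- matrix(0, w, 4)
    for (i in 1:w) for (j in 1:4) out[i, j] <- p[w + 1 - i, 5 - j]
    out
  }
  best <- -Inf
  for (bp in list(b$pfm, rc_pfm(b$pfm))) {
    wa <- nrow(a$pfm); wb <- nrow(bp)
    for (off in -(wb - 1):(wa - 1)) {
      ai <- intersect(1:wa, (1 + off):(wb + off))
      bi <- ai - off
      if (length(ai) < min_overlap) next
      va <- as.vector(a$pfm[ai, , drop = FALSE])
      vb <- as.vector(bp[bi, , drop = FALSE])
      if (stats::sd(va) > 0 && stats::sd(vb) > 0)
        best <- max(best, stats::cor(va, vb))
    }
  }
  best
}

# naive best PWM site in one sequence: explicit position/strand loops
oracle_best_site <- function(seq, motif) {
  bases <- strsplit(seq, "")[[1]]
  w <- motif$width
  L <- length(bases)
  score1 <- function(sub, pwm) {
    idx <- match(sub, c("A", "C", "G", "T"))
    if (anyNA(idx)) return(-Inf)
    s <- 0
    for (j in seq_len(w)) s <- s + pwm[j, idx[j]]
    unname(s)
  }
  pwm_rc <- motif_rc(motif)$pwm
  best <- list(position = NA, strand = NA, score = -Inf)
  for (pos in seq_len(L - w + 1)) {
    sub <- bases[pos:(pos + w - 1)]
    for (st in c("+", "-")) {
      sc <- score1(sub, if (st == "+") motif$pwm else pwm_rc)
      if (sc > best$score) best <- list(position = pos, strand = st,
                                        score = sc)
    }
  }
  best
}

# one hand-stepped ZOOPS EM iteration (E-step + M-step), explicit loops
oracle_em_step <- function(seqs, seed_kmer) {
  w <- nchar(seed_kmer)
  base_idx <- function(ch) match(ch, c("A", "C", "G", "T"))
  all_bases <- unlist(strsplit(seqs, ""))
  bg <- as.vector(table(factor(all_bases, levels = c("A", "C", "G", "T"))))
  bg <- bg / sum(bg)
  theta <- matrix(0.1, w, 4)
  sk <- base_idx(strsplit(seed_kmer, "")[[1]])
  for (j in 1:w) theta[j, sk[j]] <- 0.7
  gamma <- 0.5
  counts <- matrix(0, w, 4)
  gamma_num <- 0
  ll <- 0
  for (s in seqs) {
    b <- base_idx(strsplit(s, "")[[1]])
    L <- length(b)
    S <- L - w + 1
    m <- 2 * S
    lr <- numeric(0)
    place <- list()
    for (z in 1:S) {
      # plus strand
      v <- 0
      for (j in 1:w) v <- v + log(theta[j, b[z + j - 1]] / bg[b[z + j - 1]])
      lr <- c(lr, v)
      place[[length(place) + 1]] <- list(z = z, strand = "+")
      # minus strand: motif position j reads complement of b[z + w - j]
      v <- 0
      for (j in 1:w) {
        bb <- 5 - b[z + w - j]
        v <- v + log(theta[j, bb] / bg[b[z + w - j]])
      }
      lr <- c(lr, v)
      place[[length(place) + 1]] <- list(z = z, strand = "-")
    }
    terms <- c(log(1 - gamma), log(gamma / m) + lr)
    mx <- max(terms)
    logD <- mx + log(sum(exp(terms - mx)))
    ll <- ll + logD
    r0 <- exp(log(1 - gamma) - logD)
    gamma_num <- gamma_num + (1 - r0)
    for (iz in seq_along(lr)) {
      rz <- exp(log(gamma / m) + lr[iz] - logD)
      z <- place[[iz]]$z
      if (place[[iz]]$strand == "+") {
        for (j in 1:w) counts[j, b[z + j - 1]] <-
            counts[j, b[z + j - 1]] + rz
      } else {
        for (j in 1:w) counts[j, 5 - b[z + w - j]] <-
            counts[j, 5 - b[z + w - j]] + rz
      }
    }
  }
  gamma1 <- min(max(gamma_num / length(seqs), 1e-6), 1 - 1e-6)
  counts <- counts + 1e-8 * matrix(bg, w, 4, byrow = TRUE)
  list(ll = ll, theta = counts / rowSums(counts), gamma = gamma1)
}

# small MEME minimal fixture with a background line
write_meme_fixture <- function(path = tempfile(fileext = ".meme")) {
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    "A 0.3 C 0.2 G 0.2 T 0.3", "",
    "MOTIF M1",
    "letter-probability matrix: alength= 4 w= 3 nsites= 20 E= 0",
    "0.8 0.1 0.05 0.05",
    "0.1 0.7 0.1 0.1",
    "0.25 0.25 0.25 0.25", "",
    "MOTIF M2 ALT2",
    "letter-probability matrix: alength= 4 w= 2 nsites= 10 E= 0",
    "0.9 0.04 0.03 0.03",
    "0.05 0.05 0.05 0.85", "",
    "MOTIF M3",
    "letter-probability matrix: alength= 4 w= 4 nsites= 5 E= 0",
    "0.97 0.01 0.01 0.01",
    "0.01 0.97 0.01 0.01",
    "0.01 0.01 0.97 0.01",
    "0.01 0.01 0.01 0.97", ""), path)
  path
}

# uniform random window set, independent of the synthetic module
rand_windows <- function(n, width, seed) {
  set.seed(seed)
  window_set(sprintf("r%03d", seq_len(n)),
             vapply(seq_len(n), function(i)
               paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
                     collapse = ""), character(1)))
}
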