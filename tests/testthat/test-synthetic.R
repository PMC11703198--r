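test_that("planted datasets honor the requested gap and fraction", {
  db <- preset_motifs()
  d <- generate(plant_spec(50, window_width = 200, primary = db[["AP1"]],
                           secondary = db[["IRF"]], gap = 4,
                           plant_fraction = 1, rng_seed = 5))
  expect_true(all(d$truth$true_gap == 4))
  expect_equal(nrow(d$windows), 50L)
  expect_true(all(nchar(d$windows$seq) == 200L))
  d0 <- generate(plant_spec(50, window_width = 200, primary = db[["AP1"]],
                            secondary = db[["IRF"]], gap = 4,
                            plant_fraction = 0, rng_seed = 5))
  expect_true(all(is.na(d0$truth$true_gap)))
})

test_that("generation is byte-identical for a fixed seed", {
  db <- preset_motifs()
  sp <- plant_spec(30, window_width = 150, primary = db[["GAS"]],
                   secondary = db[["GAS"]], gap = 11, plant_fraction = 0.5,
                   rng_seed = 99)
  expect_identical(generate(sp)$windows, generate(sp)$windows)
  expect_identical(generate(sp)$truth, generate(sp)$truth)
})

test_that("truth records reproduce the planted letters under consensus plants", {
  ap1 <- motif_from_consensus("AP1", "TGACTCA")  # non-degenerate consensus
  irf <- motif_from_consensus("IRF", "TGAAAC")
  d <- generate(plant_spec(40, window_width = 120, primary = ap1,
                           secondary = irf, gap = 3,
                           quadrant = "downstream-same", plant_fraction = 1,
                           consensus_only = TRUE, rng_seed = 21))
  for (i in seq_len(40)) {
    tr <- d$truth[i, ]
    seq <- d$windows$seq[i]
    psite <- substr(seq, tr$primary_pos, tr$primary_pos + 6)
    expect_identical(if (tr$primary_strand == "+") psite else rc_str(psite),
                     "TGACTCA")
    ssite <- substr(seq, tr$secondary_pos, tr$secondary_pos + 5)
    expect_identical(if (tr$secondary_strand == "+") ssite else rc_str(ssite),
                     "TGAAAC")
    # edge-to-edge distance between the two sites equals the recorded gap
    lo <- min(tr$primary_pos, tr$secondary_pos)
    hi <- max(tr$primary_pos, tr$secondary_pos)
    wlo <- if (lo == tr$primary_pos) 7L else 6L
    expect_equal(hi - (lo + wlo), tr$true_gap)
  }
})

test_that("orientation quadrants are planted relative to the primary strand", {
  ap1 <- motif_from_consensus("AP1", "TGACTCA")
  irf <- motif_from_consensus("IRF", "TGAAAC")
  d <- generate(plant_spec(60, window_width = 120, primary = ap1,
                           secondary = irf, gap = 2,
                           quadrant = "upstream-opposite", plant_fraction = 1,
                           consensus_only = TRUE, rng_seed = 8))
  # opposite strand: secondary strand always differs from primary strand
  expect_true(all(d$truth$secondary_strand != d$truth$primary_strand))
  # upstream of the oriented primary: 5' side relative to primary orientation
  up_ok <- ifelse(d$truth$primary_strand == "+",
                  d$truth$secondary_pos < d$truth$primary_pos,
                  d$truth$secondary_pos > d$truth$primary_pos)
  expect_true(all(up_ok))
})

test_that("re-scanning emitted windows recovers the truth position", {
  d <- generate_ctcf_ets(200, seed = 13)
  m <- find_best_primary(d$windows, d$primary_motif, min_score = -Inf)
  hit <- m$position == d$truth$primary_pos & m$strand == d$truth$primary_strand
  expect_gte(mean(hit), 0.95)
})

test_that("background base frequencies match the requested composition", {
  db <- preset_motifs()
  bg <- c(0.4, 0.1, 0.1, 0.4)
  d <- generate(plant_spec(300, window_width = 400, primary = db[["AP1"]],
                           background = bg, plant_fraction = 0,
                           rng_seed = 31))
  # count bases outside the planted primary site only
  flank <- mapply(function(s, p) {
    paste0(substr(s, 1, p - 1), substr(s, p + 7, nchar(s)))
  }, d$windows$seq, d$truth$primary_pos)
  tab <- table(factor(unlist(strsplit(paste(flank, collapse = ""), "")),
                      levels = c("A", "C", "G", "T")))
  n_bases <- sum(tab)
  freq <- as.numeric(tab) / n_bases
  se <- sqrt(bg * (1 - bg) / n_bases)
  expect_true(all(abs(freq - bg) < 3 * se + 1e-9))
})

test_that("a first-order Markov background is accepted and deterministic", {
  db <- preset_motifs()
  trans <- matrix(c(0.5, 0.2, 0.2, 0.1,
                    0.25, 0.25, 0.25, 0.25,
                    0.25, 0.25, 0.25, 0.25,
                    0.1, 0.2, 0.2, 0.5), 4, 4, byrow = TRUE)
  sp <- plant_spec(40, window_width = 200, primary = db[["AP1"]],
                   background = trans, plant_fraction = 0, rng_seed = 77)
  d1 <- generate(sp)
  expect_true(all(nchar(d1$windows$seq) == 200L))
  expect_identical(d1$windows, generate(sp)$windows)
})

test_that("impossible geometries fail before any output", {
  long <- motif_from_consensus("long", strrep("A", 20))
  expect_error(plant_spec(10, window_width = 30, primary = long,
                          secondary = long, gap = 10, plant_fraction = 1),
               "cannot contain|does not fit")
  expect_error(plant_spec(10, window_width = 18, primary = long),
               "does not fit")
})

test_that("preset generators plant the documented spacings", {
  a <- generate_aice(100, seed = 7)
  expect_true(all(a$truth$true_gap[!is.na(a$truth$true_gap)] %in% c(0, 4)))
  expect_true(any(a$truth$true_gap == 0, na.rm = TRUE))
  expect_true(any(a$truth$true_gap == 4, na.rm = TRUE))
  g <- generate_gas_tetramer(100, gap = 11, seed = 7)
  expect_true(all(g$truth$true_gap[!is.na(g$truth$true_gap)] == 11))
  ce <- generate_ctcf_ets(100, seed = 7)
  expect_true(all(ce$truth$true_gap[!is.na(ce$truth$true_gap)] == 8))
})
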