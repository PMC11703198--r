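db <- preset_motifs()

test_that("the best primary match is found at the planted position", {
  ap1 <- motif_from_consensus("AP1", "TGACTCA")
  d <- generate(plant_spec(50, window_width = 200, primary = ap1,
                           primary_jitter = 40, consensus_only = TRUE,
                           rng_seed = 2))
  m <- find_best_primary(d$windows, ap1)
  expect_true(all(m$matched))
  expect_equal(m$position, d$truth$primary_pos)
  expect_equal(m$strand, d$truth$primary_strand)
  # agreement with a naive per-window scan oracle
  for (i in c(1, 17, 42)) {
    o <- oracle_best_site(d$windows$seq[i], ap1)
    expect_equal(m$position[i], o$position)
    expect_identical(m$strand[i], o$strand)
    expect_equal(m$score[i], o$score, tolerance = 1e-9)
  }
})

test_that("minus-strand plants are reported on the minus strand", {
  ap1 <- motif_from_consensus("AP1", "TGACTCA")
  set.seed(3)
  bgseq <- function() paste(sample(c("A", "C", "G", "T"), 100, TRUE),
                            collapse = "")
  s <- bgseq()
  planted <- paste0(substr(s, 1, 29), rc_str("TGACTCA"), substr(s, 37, 100))
  m <- find_best_primary(window_set("w1", planted), ap1)
  expect_identical(m$strand, "-")
  expect_equal(m$position, 30L)
})

test_that("an unreachable score threshold matches nothing", {
  d <- generate(plant_spec(20, window_width = 150, primary = db[["AP1"]],
                           rng_seed = 4))
  m <- find_best_primary(d$windows, db[["AP1"]],
                         min_score = motif_max_score(db[["AP1"]]) + 1)
  expect_false(any(m$matched))
  expect_equal(nrow(center_and_orient(d$windows, m)), 0L)
})

test_that("centering orients the primary onto the plus strand at the middle", {
  ap1 <- motif_from_consensus("AP1", "TGACTCA")
  # already centered on + with equal flanks: output must equal input
  set.seed(5)
  flank <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  flank2 <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  w <- window_set("c1", paste0(flank, "TGACTCA", flank2))
  m <- find_best_primary(w, ap1)
  cw <- center_and_orient(w, m)
  expect_identical(cw$seq, w$seq)
  expect_equal(cw$p_start, 31L)
  # a minus-strand match reads as the consensus after orientation
  wrc <- window_set("c2", rc_str(w$seq))
  m2 <- find_best_primary(wrc, ap1)
  expect_identical(m2$strand, "-")
  cw2 <- center_and_orient(wrc, m2)
  expect_identical(substr(cw2$seq, cw2$p_start, cw2$p_end), "TGACTCA")
  # round trip: re-scanning the centered window finds the primary centered
  m3 <- find_best_primary(window_set(cw2$id, cw2$seq), ap1)
  expect_identical(m3$strand, "+")
  expect_equal(m3$position, cw2$p_start)
  # primary midpoint sits within 1 bp of the window midpoint
  mid_p <- (cw2$p_start + cw2$p_end) / 2
  expect_lte(abs(mid_p - (nchar(cw2$seq) + 1) / 2), 1)
})

test_that("the best secondary site respects quadrant, gap, and overlap rules", {
  ap1 <- motif_from_consensus("AP1", "TGACTCA")
  irf <- motif_from_consensus("IRF", "TGAAAC")
  d <- generate(plant_spec(80, window_width = 200, primary = ap1,
                           secondary = irf, gap = 4, plant_fraction = 1,
                           consensus_only = TRUE, rng_seed = 6))
  m <- find_best_primary(d$windows, ap1)
  # restrict to windows centered on the planted site (a handful center on a
  # chance duplicate of the consensus elsewhere; their geometry is undefined)
  ok <- which(m$position == d$truth$primary_pos &
                m$strand == d$truth$primary_strand)
  expect_gte(length(ok), 70L)
  mo <- m[ok, , drop = FALSE]
  attr(mo, "motif_width") <- ap1$width
  cw <- center_and_orient(d$windows[ok, , drop = FALSE], mo)
  hits <- scan_secondary_best(cw, irf)
  expect_true(all(hits$gap == 4))
  expect_true(all(hits$quadrant == "downstream-same"))
  # self-pairing: the primary's own site is excluded, so the best
  # non-overlapping site lies elsewhere with a strictly legal gap
  self_hits <- scan_secondary_best(cw, ap1)
  expect_true(all(!is.na(self_hits$gap)))
  expect_true(all(self_hits$gap >= 0))
  # window exactly the size of the primary leaves no legal placement
  tiny <- structure(data.frame(id = "t", seq = "TGACTCA", p_start = 1L,
                               p_end = 7L, flank = 0L),
                    class = c("centered_windows", "data.frame"))
  expect_true(is.na(scan_secondary_best(tiny, irf)$gap))
})

test_that("histogram counts are conserved and bins legal", {
  d <- generate_aice(300, seed = 8)
  m <- find_best_primary(d$windows, d$primary_motif)
  cw <- center_and_orient(d$windows, m)
  pl <- scan_secondary_best(cw, d$secondary_motif)
  h <- spacing_histogram(pl, cw, d$secondary_motif$width)
  expect_equal(sum(h$counts$k), h$n)
  expect_equal(h$n, sum(!is.na(pl$gap)))
  max_gap <- max(cw$flank) - d$secondary_motif$width
  expect_true(all(h$counts$gap <= max_gap))
  expect_equal(h$B, 4L * (max_gap + 1L))
})

test_that("binomial tail p-values match an exact summation oracle", {
  h <- structure(list(counts = data.frame(quadrant = "downstream-same",
                                          gap = 5L, k = 20L),
                      n = 100L, B = 200L), class = "spacing_histogram")
  res <- binomial_spacing_test(h)
  expect_equal(res$p_raw, oracle_binom_tail(20, 100, 1 / 200),
               tolerance = 1e-12)
  expect_equal(res$p_adj, min(1, 200 * res$p_raw))
  # exactness up to n = 5000 at better than 1e-9 relative error
  for (case in list(c(5000, 1000, 12), c(5000, 2500, 4), c(3000, 150, 30),
                    c(750, 400, 7))) {
    n <- case[1]; B <- case[2]; k <- case[3]
    hh <- structure(list(counts = data.frame(quadrant = "upstream-same",
                                             gap = 0L, k = as.integer(k)),
                         n = as.integer(n), B = as.integer(B)),
                    class = "spacing_histogram")
    got <- binomial_spacing_test(hh)$p_raw
    want <- oracle_binom_tail(k, n, 1 / B)
    expect_lt(abs(got - want) / want, 1e-9)
  }
  # a single bin absorbs all the mass: p_raw = 1
  h1 <- structure(list(counts = data.frame(quadrant = "upstream-same",
                                           gap = 0L, k = 10L),
                       n = 10L, B = 1L), class = "spacing_histogram")
  expect_equal(binomial_spacing_test(h1)$p_raw, 1)
  h0 <- structure(list(counts = data.frame(quadrant = character(),
                                           gap = integer(), k = integer()),
                       n = 10L, B = 0L), class = "spacing_histogram")
  expect_error(binomial_spacing_test(h0), "B = 0")
})

test_that("pair E-values scale the best adjusted p-value by database size", {
  expect_equal(pair_evalue(0.003, 1), 0.003)
  expect_equal(pair_evalue(1e-12, 401), 4.01e-10)
  e <- vapply(c(1, 10, 100, 401), pair_evalue, numeric(1),
              best_p_adj = 1e-6)
  expect_true(all(diff(e) > 0))
  expect_error(pair_evalue(0.5, 0), ">= 1")
})

test_that("pair analysis recovers planted composite spacings", {
  db <- preset_motifs()
  d4 <- generate(plant_spec(600, primary = db[["AP1"]],
                            secondary = db[["IRF"]], gap = 4,
                            plant_fraction = 0.6, rng_seed = 31))
  f4 <- analyze_pair(d4$windows, db[["AP1"]], db[["IRF"]])
  expect_equal(f4$best$gap, 4L)
  # palindromic primary: either of the two symmetric quadrants is correct
  expect_true(f4$best$quadrant %in% c("downstream-same",
                                      "upstream-opposite"))
  expect_lt(f4$best$p_adj, 1e-10)
  # self-pairing at the tetramer spacing
  g <- generate_gas_tetramer(600, gap = 11, seed = 32)
  fg <- analyze_pair(g$windows, g$primary_motif, g$primary_motif)
  expect_equal(fg$best$gap, 11L)
})

test_that("shifting the planted gap by one moves the modal bin by one", {
  db <- preset_motifs()
  for (g in c(6L, 7L)) {
    d <- generate(plant_spec(400, primary = db[["CTCF"]],
                             secondary = db[["ETS"]], gap = g,
                             plant_fraction = 0.6, rng_seed = 33))
    expect_equal(analyze_pair(d$windows, db[["CTCF"]],
                              db[["ETS"]])$best$gap, g)
  }
})

test_that("quadrant pooling and scan margins behave consistently", {
  db <- preset_motifs()
  d <- generate(plant_spec(400, primary = db[["CTCF"]],
                           secondary = db[["ETS"]], gap = 8,
                           plant_fraction = 0.6, rng_seed = 61))
  full <- analyze_pair(d$windows, db[["CTCF"]], db[["ETS"]])
  pooled <- analyze_pair(d$windows, db[["CTCF"]], db[["ETS"]],
                         pool_quadrants = TRUE)
  expect_equal(pooled$best$gap, full$best$gap)
  expect_identical(pooled$best$quadrant, "pooled")
  expect_equal(sum(pooled$hist$counts$k), pooled$n)
  # pooled bin probability 4/B: an even split across quadrants at one gap
  # is unremarkable pooled but would be 4 separate observations otherwise
  expect_equal(pooled$hist$B, full$hist$B)
  # a margin restricts placements and shrinks the bin universe
  near <- analyze_pair(d$windows, db[["CTCF"]], db[["ETS"]], margin = 20)
  expect_lte(max(near$hist$counts$gap), 20)
  expect_equal(near$hist$B, 4L * 21L)
  expect_equal(near$best$gap, 8L)
})

test_that("results are invariant to reverse-complementing every window", {
  d <- generate_ctcf_ets(250, seed = 35)
  f1 <- analyze_pair(d$windows, d$primary_motif, d$secondary_motif)
  wrc <- window_set(d$windows$id,
                    as.character(Biostrings::reverseComplement(
                      Biostrings::DNAStringSet(d$windows$seq))))
  f2 <- analyze_pair(wrc, d$primary_motif, d$secondary_motif)
  expect_equal(f1$best$gap, f2$best$gap)
  expect_equal(f1$best$p_adj, f2$best$p_adj)
  expect_equal(f1$evalue, f2$evalue)
  expect_identical(f1$best$quadrant, f2$best$quadrant)
  expect_equal(f1$hist$counts, f2$hist$counts)
})

test_that("windows without a primary match give an empty flag, not an error", {
  w <- rand_windows(10, 100, seed = 36)
  f <- analyze_pair(w, preset_motifs()[["CTCF"]], preset_motifs()[["ETS"]],
                    min_score = 1e6)
  expect_true(f$empty)
  expect_equal(f$n, 0L)
})

test_that("library screening ranks the planted partner first", {
  db <- preset_motifs()
  extra <- motif_db(c(db$motifs,
                      lapply(6:10, function(i)
                        rand_motif(8, i, paste0("RND", i)))))
  d <- generate(plant_spec(500, primary = db[["AP1"]],
                           secondary = db[["IRF"]], gap = 4,
                           plant_fraction = 0.6, rng_seed = 37))
  scr <- analyze_library(d$windows, db[["AP1"]], extra)
  expect_identical(scr$significant$secondary[1], "IRF")
  expect_equal(scr$significant$gap[1], 4L)
  # E-values use the database size
  expect_equal(scr$table$evalue, scr$table$p_adj * length(extra))
  # alpha = 0 retains nothing
  expect_equal(nrow(analyze_library(d$windows, db[["AP1"]], extra,
                                    alpha = 0)$significant), 0L)
  # ranking is invariant to database order
  perm <- motif_db(extra$motifs[rev(seq_along(extra$motifs))])
  scr2 <- analyze_library(d$windows, db[["AP1"]], perm)
  expect_equal(scr2$table[order(scr2$table$secondary), ],
               scr$table[order(scr$table$secondary), ],
               ignore_attr = TRUE)
})

test_that("the null spacing test is conservative at alpha = 0.01", {
  db <- preset_motifs()
  n_rep <- 60
  hits <- vapply(seq_len(n_rep), function(s) {
    d <- generate(plant_spec(120, window_width = 240,
                             primary = db[["AP1"]], secondary = db[["IRF"]],
                             plant_fraction = 0, rng_seed = 5000 + s))
    analyze_pair(d$windows, db[["AP1"]], db[["IRF"]])$best$p_adj < 0.01
  }, logical(1))
  expect_lte(mean(hits), 0.01 + 1e-12)
})
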