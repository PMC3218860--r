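test_that("uniform tracks yield no accessible regions", {
  trk <- toy_track(rep(5, 5000))
  expect_equal(nrow(call_accessible_regions(trk, fdr = 0.05)), 0)
  expect_equal(nrow(call_accessible_regions(trk, fdr = 0.4)), 0)
  expect_error(call_accessible_regions(trk, fdr = 1.2), "fdr")
  # an all-zero track is a valid empty result, not an error
  expect_equal(nrow(call_accessible_regions(toy_track(rep(0, 1000)))), 0)
})

test_that("a single strongly enriched region is recovered near-exactly", {
  cfg <- simulation_config(seed = 31, genome = genome_spec("chr1", 1e6),
                           n_accessible = 0)
  region <- intervals("chr1", 500000, 501000)
  trk <- simulate_dnase_tracks(cfg, region, strengths = 10,
                               n_replicates = 1, seed = 88)[[1]]
  called <- call_accessible_regions(trk, fdr = 0.05)
  expect_equal(nrow(called), 1)
  expect_lt(abs(called$start - 500000), 200)
  expect_lt(abs(called$end - 501000), 200)
  expect_lte(called$qvalue, 0.05)
  expect_gte(called$score, 100)   # ~10x over lambda 2/bin in a 160-bp window
})

test_that("region statistics come from constituent windows", {
  set.seed(12)
  counts <- rpois(2500, 2)
  counts[1000:1050] <- rpois(51, 30)
  trk <- toy_track(counts)
  called <- call_accessible_regions(trk, fdr = 0.05)
  expect_equal(nrow(called), 1)
  expect_true(called$pvalue <= called$qvalue)
  expect_gte(called$score, max(counts[1000:1050]))
})

test_that("concordance keeps intersected replicate-1 regions", {
  r1 <- call_accessible_regions(toy_track(c(rep(2, 200), rep(60, 20),
                                            rep(2, 200))))
  expect_identical(concordant_regions(r1, r1)[, c("start", "end")],
                   r1[, c("start", "end")])
  empty <- r1[0, ]
  expect_equal(nrow(concordant_regions(r1, empty)), 0)

  a <- r1[1, ]; a$start <- 100; a$end <- 300
  b <- r1[1, ]; b$start <- 200; b$end <- 400
  out <- concordant_regions(a, b)
  expect_equal(c(out$start, out$end), c(200, 300))
  expect_equal(out$score, a$score)  # replicate-1 statistics retained
})

test_that("peak detection respects the 75-bp local-maximum rule", {
  # monotonic ramp: single peak at the high end
  ramp <- toy_track(1:50)
  rg <- intervals("chr1", 0, 1000)
  pk <- detect_peaks(ramp, rg)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$density, 50)

  # two equal summits 200 bp apart -> two peaks
  v <- rep(1, 50); v[10] <- 9; v[20] <- 9
  pk <- detect_peaks(toy_track(v), rg)
  expect_equal(nrow(pk), 2)

  # two equal summits 60 bp apart -> leftmost only
  v <- rep(1, 50); v[10] <- 9; v[13] <- 9
  pk <- detect_peaks(toy_track(v), rg)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$position, 9 * 20 + 10)

  # region shorter than one window still yields one peak
  pk <- detect_peaks(toy_track(c(3, 7)), intervals("chr1", 0, 30))
  expect_equal(nrow(pk), 1)
})

test_that("peak ranking is density-descending with positional tie-break", {
  pk <- data.frame(chrom = "chr1", position = c(10, 200, 100, 400),
                   density = c(3, 9, 9, 1), region = 1:4)
  rk <- rank_peaks(pk)
  expect_equal(rk$position, c(100, 200, 10, 400))
  expect_equal(nrow(rank_peaks(pk[0, ])), 0)
  # permutation invariance
  set.seed(3)
  expect_equal(rank_peaks(pk[sample(4), ]), rk)
})

test_that("peak calls translate with the track", {
  set.seed(77)
  counts <- rpois(500, 2); counts[200:220] <- rpois(21, 40)
  t1 <- toy_track(counts)
  shift <- 50  # bins
  t2 <- toy_track(c(rep(2, shift), counts))
  r1 <- call_accessible_regions(t1)
  r2 <- call_accessible_regions(t2)
  p1 <- detect_peaks(t1, r1)
  p2 <- detect_peaks(t2, r2)
  expect_equal(p2$position, p1$position + shift * 20)
  expect_equal(p2$density, p1$density)
})

test_that("window-level BH matches a hand-rolled q-value oracle", {
  set.seed(21)
  p <- runif(500)^2
  n <- length(p)
  o <- order(p)
  q_oracle <- numeric(n)
  q_oracle[o] <- rev(cummin(rev(p[o] * n / seq_len(n))))
  expect_equal(stats::p.adjust(p, "BH"), pmin(q_oracle, 1))
})
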