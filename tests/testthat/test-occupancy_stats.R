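test_that("median notch CI collapses for constant or singleton input", {
  expect_equal(unname(median_ci(rep(4.2, 10))), c(4.2, 4.2, 4.2))
  expect_equal(unname(median_ci(7)), c(7, 7, 7))
  expect_error(median_ci(numeric(0)), "empty")
})

test_that("median notch CI matches the independent hinge oracle", {
  set.seed(14)
  for (rep in 1:200) {
    v <- rnorm(sample(2:60, 1), sd = sample(1:5, 1))
    expect_equal(unname(median_ci(v)), hinge_notch_oracle(v),
                 tolerance = 1e-12)
  }
})

test_that("the 200-bp / encompassment overlap rule is applied per peak", {
  peak <- data.frame(chrom = "chr1", start = 0, end = 1000)
  # 150 bp overlap and not contained: not counted
  ov <- chip_overlap_fraction(peak, intervals("chr1", 850, 1050))
  expect_equal(ov$fraction, 0)
  # exactly 200 bp: counted
  ov <- chip_overlap_fraction(peak, intervals("chr1", 800, 1200))
  expect_equal(ov$fraction, 1)
  # contained region with only 100 bp of overlap: counted
  ov <- chip_overlap_fraction(peak, intervals("chr1", 400, 500))
  expect_equal(ov$fraction, 1)
  # regions covering the genome: fraction 1
  ov <- chip_overlap_fraction(peak, intervals("chr1", 0, 5000))
  expect_equal(ov$fraction, 1)
  expect_error(chip_overlap_fraction(peak[0, ], intervals("chr1", 0, 10)),
               "no peaks")
})

test_that("overlap counting is order-invariant", {
  set.seed(6)
  peaks <- data.frame(chrom = "chr1",
                      start = seq(0, 90000, by = 3000))
  peaks$end <- peaks$start + 1000
  rg <- random_intervals(40, genome_len = 95000, max_len = 900)
  f1 <- chip_overlap_fraction(peaks, rg)$fraction
  f2 <- chip_overlap_fraction(peaks[sample(nrow(peaks)), ],
                              rg[sample(nrow(rg)), ])$fraction
  expect_equal(f1, f2)
})

test_that("hypergeometric overlap p-values match exact enumeration", {
  expect_equal(hypergeom_overlap_pvalue(100, 10, 20, 0), 1)
  expect_equal(hypergeom_overlap_pvalue(10, 2, 5, 2), 10 / 45,
               tolerance = 1e-12)
  expect_error(hypergeom_overlap_pvalue(10, 2, 5, 3), "overlap")
  expect_error(hypergeom_overlap_pvalue(10, 12, 5, 2), "genome")
  # monotone decreasing in q
  ps <- vapply(0:5, function(q) hypergeom_overlap_pvalue(50, 10, 12, q), 0)
  expect_true(all(diff(ps) < 0))
})

test_that("binding coverage honours the 75-bp boundary rule", {
  g <- genome_spec("chr1", 100000)
  pk <- data.frame(chrom = "chr1", position = c(10000, 20000, 30000),
                   density = c(9, 5, 1), region = 1:3)
  none <- binding_coverage_of_peaks(pk, data.frame(chrom = character(0),
                                                   position = numeric(0)),
                                    g, cohort_size = 3)
  expect_equal(none$fraction_covered, 0)
  # merged padded chip region ends at 20500+500+1; peak 75 bp past the edge
  chip <- data.frame(chrom = "chr1", position = 20500)
  cov <- binding_coverage_of_peaks(
    data.frame(chrom = "chr1", position = c(20500 + 500 + 1 + 74), density = 1,
               region = 1), chip, g, cohort_size = 1)
  expect_equal(cov$fraction_covered, 1)
  cov <- binding_coverage_of_peaks(
    data.frame(chrom = "chr1", position = c(20500 + 500 + 1 + 76), density = 1,
               region = 1), chip, g, cohort_size = 1)
  expect_equal(cov$fraction_covered, 0)
})

test_that("rank curves reproduce constants and flag partial cohorts", {
  trk <- toy_track(rep(4, 5000))
  set.seed(2)
  pk <- data.frame(chrom = "chr1",
                   peak_position = sample(2000:98000, 450),
                   score = runif(450))
  pk$start <- pk$peak_position - 500
  pk$end <- pk$peak_position + 500
  expect_warning(
    cv <- chip_rank_accessibility_curves(pk[1:150, ], list(s1 = trk),
                                         intervals("chr1", 0, 100000),
                                         cohort_size = 200),
    "partial")
  cv <- chip_rank_accessibility_curves(pk, list(s1 = trk),
                                       intervals("chr1", 0, 100000))
  expect_true(all(cv$median == 4))
  expect_true(all(cv$fraction_overlapping == 1))
  expect_equal(sum(!cv$partial), 2)
  expect_equal(cv$n[cv$partial], 50)
})

test_that("chip score surface answers max-in-window queries with a floor", {
  peaks <- data.frame(chrom = "chr1", start = c(1000, 1600),
                      end = c(2000, 2600), score = c(5, 9))
  surf <- chip_score_surface(peaks)
  expect_equal(max_chip_score(surf, "chr1", 1500, 50), 5)
  expect_equal(max_chip_score(surf, "chr1", 1700, 50), 9)
  expect_equal(max_chip_score(surf, "chr1", 50000, 100), 5)  # floor
  expect_equal(max_chip_score(surf, "chr1", 2599 + 250, 250), 9)
  expect_equal(max_chip_score(surf, "chr1", 2600 + 251, 250), 5)
})

test_that("cohort summaries are invariant to order-preserving score maps", {
  st <- default_study()
  acc <- default_regions()
  ch <- st$chip$stage1
  pk <- chip_fdr_subset(ch[ch$factor == "TF02", ], "25%")
  tr <- list(stage1 = st$tracks$stage1[[1]])
  cv1 <- chip_rank_accessibility_curves(pk, tr, acc)
  pk2 <- pk
  pk2$score <- log(pk$score + 1)  # monotone transform
  cv2 <- chip_rank_accessibility_curves(pk2, tr, acc)
  expect_equal(cv1$median, cv2$median)
  expect_equal(cv1$fraction_overlapping, cv2$fraction_overlapping)
})

test_that("affinity table classifies compartments by match midpoint", {
  surf <- chip_score_surface(data.frame(chrom = "chr1", start = 1000,
                                        end = 2000, score = 8),
                             floor_score = 1)
  matches <- data.frame(factor = "f", chrom = "chr1",
                        mid = c(1500, 5000), logodds = 10,
                        cohort = c(-5L, -5L))
  acc <- intervals("chr1", 1400, 1600)
  tab <- affinity_cohort_analysis(matches, matches[0, ], acc, surf)
  g5 <- tab[tab$motif_kind == "genuine" & tab$cohort == -5, ]
  expect_equal(g5$n[g5$compartment == "accessible"], 1L)
  expect_equal(g5$n[g5$compartment == "closed"], 1L)
  expect_equal(g5$median[g5$compartment == "accessible"], 8)
  expect_equal(g5$median[g5$compartment == "closed"], 1)
  # no accessible regions: everything is closed
  tab0 <- affinity_cohort_analysis(matches, matches[0, ], acc[0, ], surf)
  expect_equal(sum(tab0$n[tab0$compartment == "accessible"]), 0L)
})

test_that("rank-matrix correlations hit 1 when ChIP equals density", {
  set.seed(8)
  pk <- data.frame(chrom = "chr1", position = seq(1000, 999000, by = 2000),
                   density = NA, region = 1)
  pk$density <- sort(rexp(nrow(pk)) * 50, decreasing = TRUE)
  chip <- data.frame(chrom = "chr1", start = pk$position - 50,
                     end = pk$position + 50, score = pk$density)
  surf <- chip_score_surface(chip, floor_score = 0)
  rm <- accessibility_rank_matrix(
    pk, list(f1 = surf),
    list(f1 = data.frame(chrom = character(0), mid = numeric(0))),
    near_bp = 49)
  expect_equal(rm$correlations$r_chip, 1, tolerance = 1e-12)
  expect_true(is.na(rm$correlations$r_count))  # no matches: undefined
})
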