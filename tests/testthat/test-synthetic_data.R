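test_that("identical seeds reproduce the study byte-for-byte", {
  cfg <- function() simulation_config(seed = 15, n_factors = 2,
                                      genome = genome_spec("chrA", 3e5),
                                      n_accessible = 40,
                                      planted_per_tier = c("-5" = 5))
  a <- simulate_study(cfg())
  b <- simulate_study(cfg())
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c <- simulate_study(simulation_config(seed = 16, n_factors = 2,
                                        genome = genome_spec("chrA", 3e5),
                                        n_accessible = 40,
                                        planted_per_tier = c("-5" = 5)))
  expect_false(identical(a$sequence, c$sequence))
})

test_that("degenerate PWMs plant their consensus at recorded positions", {
  aa <- consensus_pwm("AAAAAAAA", "polyA", dominant = 1)
  cfg <- simulation_config(seed = 3, genome = genome_spec("chr1", 50000),
                           n_accessible = 0, pwm_set = list(aa),
                           n_factors = 1,
                           planted_per_tier = c("-5" = 0),
                           planted_per_tier_closed = c("-5" = 10))
  gen <- simulate_genome(cfg)
  expect_equal(nrow(gen$planted), 10)
  for (i in seq_len(10)) {
    site <- unname(substr(gen$sequence, gen$planted$start[i] + 1,
                          gen$planted$end[i]))
    if (gen$planted$strand[i] == "-") site <- accessmap:::revcomp_seq(site)
    expect_equal(site, "AAAAAAAA")
  }
})

test_that("background base composition matches the stated frequencies", {
  cfg <- simulation_config(seed = 9, genome = genome_spec("chr1", 4e5),
                           n_accessible = 0,
                           planted_per_tier = c("-5" = 0))
  gen <- simulate_genome(cfg)
  counts <- tabulate(accessmap:::seq_to_codes(gen$sequence), 4)
  n <- sum(counts)
  sd3 <- 3 * sqrt(n * 0.25 * 0.75)
  expect_true(all(abs(counts - n * 0.25) < sd3))
})

test_that("DNase tracks have the programmed means and concordant replicates", {
  cfg <- simulation_config(seed = 5, genome = genome_spec("chr1", 1e6),
                           lambda_bg = 1)
  # null track: mean ~ lambda genome-wide
  t0 <- simulate_dnase_tracks(cfg, empty_region_set <- intervals(
    character(0), numeric(0), numeric(0)), numeric(0),
    n_replicates = 1, seed = 2)[[1]]
  m <- mean(t0$counts$chr1)
  expect_lt(abs(m - 1), 3 * sqrt(1 / length(t0$counts$chr1)))

  # A = 20 region: in-region mean ~ 20 x lambda
  rg <- intervals("chr1", 200000, 210000)
  tr <- simulate_dnase_tracks(cfg, rg, strengths = 20, n_replicates = 2,
                              seed = 7)
  bins <- (200000 / 20 + 1):(210000 / 20)
  mu <- mean(tr[[1]]$counts$chr1[bins])
  expect_lt(abs(mu - 20), 3 * sqrt(20 / length(bins)))

  # replicates agree on per-region signal when strengths vary
  starts <- seq(0, 980000, by = 20000)
  many <- intervals("chr1", starts, starts + 2000)
  A <- 10^runif(length(starts), log10(2), log10(50))
  tr2 <- simulate_dnase_tracks(cfg, many, A, n_replicates = 2, seed = 9)
  per_region <- function(trk) vapply(seq_along(starts), function(i)
    mean(trk$counts$chr1[(starts[i] / 20 + 1):((starts[i] + 2000) / 20)]),
    0)
  expect_gt(cor(per_region(tr2[[1]]), per_region(tr2[[2]])), 0.9)
})

test_that("occupancy model arithmetic is exact at zero noise", {
  g <- genome_spec("chr1", 100000)
  m <- consensus_pwm("ACGTACGT", "f1")
  # one identical site in an A=10 region and one in closed chromatin
  cfg <- simulation_config(seed = 1, genome = g, pwm_set = list(m),
                           n_factors = 1, chip_noise_sigma = 0,
                           residual_affinity = 0,
                           n_background_windows = 0)
  rg <- intervals("chr1", 20000, 22000)
  sites <- data.frame(chrom = "chr1", mid = c(21000, 61000),
                      logodds = 10, factor = "f1")
  pk <- simulate_chip_scores(cfg, rg, sites, m, strengths = 10, seed = 4)
  expect_equal(nrow(pk), 2)
  expect_equal(max(pk$score) / min(pk$score), 10, tolerance = 1e-12)
  expect_equal(pk$score, pk$occupancy)  # zero noise: reported = raw

  # two equal sites in one window vs one site: ratio exactly 2 when the
  # fragment-size kernel is disabled (pure additivity)
  sites2 <- data.frame(chrom = "chr1", mid = c(61000, 61100, 81000),
                       logodds = 10, factor = "f1")
  pk2 <- simulate_chip_scores(cfg, rg[0, ], sites2, m, strengths = numeric(0),
                              seed = 4, resolution_bp = Inf)
  expect_equal(max(pk2$score) / min(pk2$score), 2, tolerance = 1e-12)
})

test_that("reported scores track true occupancy under log-normal noise", {
  st <- default_study()
  ch <- st$chip$stage1
  one <- ch[ch$factor == "TF01", ]
  expect_gt(nrow(one), 1500)
  expect_gt(cor(rank(one$occupancy), rank(one$score)), 0.9)
})

test_that("stage two applies the programmed modulations", {
  cfg <- simulation_config(seed = 44, n_factors = 2,
                           genome = genome_spec("chr1", 5e5),
                           n_accessible = 50, chip_noise_sigma = 0,
                           modulation_range = c(0.1, 0.1),
                           change_fraction = 1)
  st <- simulate_study(cfg)
  expect_equal(st$regions$strength_stage2,
               st$regions$strength_stage1 * st$regions$modulation)
  bin <- cfg$bin_size
  i <- which.max(st$regions$strength_stage1)
  bins <- (floor(st$regions$start[i] / bin) + 2):
    (floor(st$regions$end[i] / bin) - 1)
  m1 <- mean(st$tracks$stage1[[1]]$counts$chr1[bins])
  m2 <- mean(st$tracks$stage2[[1]]$counts$chr1[bins])
  expect_lt(abs(m2 / m1 - 0.1), 0.05)

  # no-change configuration: stage tracks differ only by counting noise
  cfg0 <- simulation_config(seed = 44, n_factors = 2,
                            genome = genome_spec("chr1", 5e5),
                            n_accessible = 50, change_fraction = 0)
  st0 <- simulate_study(cfg0)
  expect_true(all(st0$regions$modulation == 1))
  expect_lt(abs(mean(st0$tracks$stage2[[1]]$counts$chr1) -
                  mean(st0$tracks$stage1[[1]]$counts$chr1)), 0.1)
})

test_that("planted sites land in their intended cohorts when re-scanned", {
  st <- default_study()
  pl <- st$planted
  got <- integer(nrow(pl))
  for (f in unique(pl$factor)) {
    idx <- which(pl$factor == f)
    d <- st$dists[[f]]
    p <- score_pvalue(d, pl$logodds[idx])
    got[idx] <- assign_cohort(p)
  }
  expect_gte(mean(got == pl$cohort), 0.95)
})

test_that("studies serialize to the standard formats and read back", {
  cfg <- simulation_config(seed = 15, n_factors = 2,
                           genome = genome_spec("chrA", 2e5),
                           n_accessible = 20,
                           planted_per_tier = c("-5" = 5))
  st <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_equal(as.character(seqs[["chrA"]]), st$sequence[["chrA"]])
  trk <- read_bedgraph_as_track(file.path(dir, "dnase_stage1_rep1.bedGraph"),
                                cfg$genome, cfg$bin_size)
  expect_equal(trk$counts, st$tracks$stage1[[1]]$counts)
  pw <- read_meme_minimal(file.path(dir, "motifs.meme"))
  expect_equal(pw[[1]]$probs, st$pwms[[1]]$probs, tolerance = 1e-5)
  expect_equal(nrow(read_bed(file.path(dir, "truth_regions.bed"))),
               nrow(st$regions))
})
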