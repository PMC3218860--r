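test_that("MEME minimal format round-trips and validates", {
  set.seed(2)
  pwms <- random_pwms(3, width = 6, seed = 11)
  f <- withr::local_tempfile()
  write_meme_minimal(pwms, f)
  back <- read_meme_minimal(f)
  expect_length(back, 3)
  expect_equal(vapply(back, function(m) m$name, ""),
               vapply(pwms, function(m) m$name, ""))
  for (k in 1:3)
    expect_equal(back[[k]]$probs, pwms[[k]]$probs, tolerance = 1e-5)

  writeLines(c("MEME version 4", "ALPHABET= ACGU", "MOTIF x",
               "letter-probability matrix: alength= 4 w= 4",
               rep("0.25 0.25 0.25 0.25", 4)), f)
  expect_error(read_meme_minimal(f), "alphabet")
  expect_error(pwm("bad", matrix(c(0.9, 0.3, 0.1, 0.1), 4, 4)), "sum")
})

test_that("exact score distribution matches brute-force enumeration", {
  for (w in 4:6) {
    m <- random_pwms(1, width = w, seed = 20 + w)[[1]]
    bg <- c(0.3, 0.2, 0.2, 0.3)
    d <- score_to_pvalue(m, bg)
    smat <- accessmap:::logodds_matrix(m, bg)
    words <- as.matrix(expand.grid(rep(list(1:4), w)))
    sc <- rowSums(matrix(smat[cbind(rep(seq_len(w), each = nrow(words)),
                                    as.vector(words))], ncol = w))
    pr <- apply(matrix(bg[words], ncol = w), 1, prod)
    # compare tails at thresholds between adjacent achievable scores,
    # avoiding ambiguity from ties at float precision
    g <- sort(unique(round(sc, 6)))
    thr <- c(g[1] - 1, (g[-1] + g[-length(g)]) / 2)
    for (q in thr)
      expect_lt(abs(score_pvalue(d, q) - sum(pr[sc > q])), 1e-9)
  }
})

test_that("tail probabilities are monotone and total mass is one", {
  m <- random_pwms(1, width = 8, seed = 4)[[1]]
  d <- score_to_pvalue(m)
  expect_equal(d$tail[1], 1, tolerance = 1e-12)
  expect_true(all(diff(d$tail) <= 1e-15))
  expect_equal(score_pvalue(d, min(d$scores)), 1, tolerance = 1e-12)
})

test_that("scanning finds planted consensus sites with correct coordinates", {
  aa <- consensus_pwm("AAAAAA")
  res <- scan_pwm(c(chr1 = "TTAAAAAATT"), aa, p_threshold = 0.001,
                  background = "uniform")
  expect_equal(nrow(res), 1)
  expect_equal(res$start, 2)
  expect_equal(res$end, 8)
  expect_equal(res$strand, "+")
  expect_equal(res$pvalue, 0.25^6, tolerance = 1e-12)

  expect_equal(nrow(scan_pwm(c(chr1 = ""), aa)), 0)
  # windows containing N are skipped
  resN <- scan_pwm(c(chr1 = "TTAANAAATT"), aa, p_threshold = 0.001,
                   background = "uniform")
  expect_equal(nrow(resN), 0)
})

test_that("match sets reflect under reverse complement of the sequence", {
  set.seed(8)
  m <- random_pwms(1, width = 5, seed = 31)[[1]]
  s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
             collapse = "")
  fwd <- scan_pwm(c(chr1 = s), m, 0.04, background = "uniform")
  rev <- scan_pwm(c(chr1 = accessmap:::revcomp_seq(s)), m, 0.04,
                  background = "uniform")
  # start on the reflected sequence = len - end
  key <- function(start, lo) sort(paste(start, round(lo, 9)))
  expect_equal(key(400 - rev$end, rev$logodds),
               key(fwd$start, fwd$logodds))
})

test_that("lower thresholds give subsets of matches", {
  set.seed(9)
  m <- random_pwms(1, width = 6, seed = 77)[[1]]
  s <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
             collapse = "")
  hi <- scan_pwm(c(chr1 = s), m, 0.04, background = "uniform")
  lo <- scan_pwm(c(chr1 = s), m, 0.003, background = "uniform")
  expect_lte(nrow(lo), nrow(hi))
  expect_true(all(paste(lo$start, lo$strand) %in%
                    paste(hi$start, hi$strand)))
  expect_true(all(lo$pvalue < 0.003))
})

test_that("affinity cohorts follow the stated p-value bins and boundaries", {
  expect_equal(assign_cohort(c(1e-5, 1e-4, 1e-3, 1e-2)),
               c(-5L, -4L, -3L, -2L))
  expect_equal(assign_cohort(10^-4.5), -4L)  # boundary to the looser cohort
  expect_equal(assign_cohort(10^-3.5), -3L)
  expect_equal(assign_cohort(10^-2.5), -2L)
  expect_error(assign_cohort(0.05))
  expect_error(assign_cohort(0))
})

test_that("self-similarity is maximal and the statistic is symmetric", {
  m <- random_pwms(2, width = 7, seed = 13)
  p_self <- motif_similarity_pvalue(m[[1]], m[[1]], n_perm = 200, seed = 1)
  expect_equal(p_self, 1 / 201)
  expect_equal(motif_similarity_stat(m[[1]], m[[2]]),
               motif_similarity_stat(m[[2]], m[[1]]), tolerance = 1e-12)
})

test_that("unrelated uniform-column motifs are rarely called similar", {
  m <- random_pwms(1, width = 8, seed = 3)[[1]]
  hits <- 0
  for (s in 1:10) {
    u <- with_seed_local <- accessmap:::with_seed(1000 + s, {
      probs <- matrix(stats::rgamma(32, 1), 8, 4)
      pwm("unif", probs / rowSums(probs))
    })
    p <- motif_similarity_pvalue(m, u, n_perm = 200, seed = 500 + s)
    if (p > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("scrambles preserve column content and reject similar candidates", {
  m <- random_pwms(1, width = 8, seed = 6)[[1]]
  others <- random_pwms(3, width = 8, seed = 60)
  scr <- scramble_pwm(m, n = 10, others = others, alpha = 0.05, seed = 42,
                      n_perm = 99)
  expect_length(scr, 10)
  keyset <- function(p) sort(apply(round(p, 10), 1, paste, collapse = ","))
  for (s in scr) {
    expect_equal(keyset(s$probs), keyset(m$probs))
    expect_false(isTRUE(all.equal(s$probs, m$probs,
                                  check.attributes = FALSE)))
  }
  # all scrambles distinct
  sigs <- vapply(scr, function(s) paste(round(s$probs, 8), collapse = ","),
                 "")
  expect_equal(anyDuplicated(sigs), 0L)

  flat <- pwm("flat", matrix(rep(c(0.7, 0.1, 0.1, 0.1), 5), 5, 4,
                             byrow = TRUE))
  expect_error(scramble_pwm(flat, n = 3, seed = 1, max_tries = 50),
               "scramble")
})
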