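# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# Default synthetic study (the package's standard study conditions).
default_study <- function() {
  if (is.null(.fixtures$study)) {
    .fixtures$study <- simulate_study(simulation_config(seed = 7))
  }
  .fixtures$study
}

# Concordant 5% FDR accessible regions of the default study, stage 1.
default_regions <- function() {
  if (is.null(.fixtures$regions)) {
    st <- default_study()
    r1 <- call_accessible_regions(st$tracks$stage1[[1]])
    r2 <- call_accessible_regions(st$tracks$stage1[[2]])
    .fixtures$regions <- concordant_regions(r1, r2)
  }
  .fixtures$regions
}

# Integer-coded chromosomes of the default study (scan input).
default_codes <- function() {
  if (is.null(.fixtures$codes)) {
    .fixtures$codes <- lapply(default_study()$sequence,
                              accessmap:::seq_to_codes)
  }
  .fixtures$codes
}

# a tiny single-chromosome genome and track from raw bin counts
toy_track <- function(counts, bin = 20, chrom = "chr1") {
  g <- genome_spec(chrom, length(counts) * bin)
  tag_track(g, bin, stats::setNames(list(as.numeric(counts)), chrom))
}

# strongly informative degenerate PWM (one dominant base per column)
consensus_pwm <- function(word, name = "toy", dominant = 0.97) {
  letters <- strsplit(word, "")[[1]]
  probs <- t(vapply(letters, function(l) {
    p <- rep((1 - dominant) / 3, 4)
    p[match(l, c("A", "C", "G", "T"))] <- dominant
    p
  }, numeric(4)))
  pwm(name, probs)
}

random_intervals <- function(n, genome_len = 10000, max_len = 500,
                             chrom = "chr1") {
  start <- sample.int(genome_len - max_len, n, replace = TRUE) - 1
  len <- sample.int(max_len, n, replace = TRUE)
  intervals(chrom, start, pmin(start + len, genome_len))
}

# per-bp boolean mask union oracle for merge_intervals
mask_merge_oracle <- function(x, max_gap, genome_len) {
  mask <- logical(genome_len)
  for (i in seq_len(nrow(x))) mask[(x$start[i] + 1):x$end[i]] <- TRUE
  if (max_gap > 0) {
    r <- rle(mask)
    gap <- which(!r$values & r$lengths <= max_gap)
    gap <- gap[gap > 1 & gap < length(r$values)]
    r$values[gap] <- TRUE
    mask <- inverse.rle(r)
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

# independent Tukey-hinge / notch oracle for median_ci
hinge_notch_oracle <- function(v) {
  v <- sort(v)
  n <- length(v)
  med <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  half <- if (n %% 2 == 1) v[1:((n + 1) / 2)] else v[1:(n / 2)]
  upper <- if (n %% 2 == 1) v[((n + 1) / 2):n] else v[(n / 2 + 1):n]
  hmed <- function(u) {
    m <- length(u)
    if (m %% 2 == 1) u[(m + 1) / 2] else (u[m / 2] + u[m / 2 + 1]) / 2
  }
  iqr <- hmed(upper) - hmed(half)
  c(med, med - 1.58 * iqr / sqrt(n), med + 1.58 * iqr / sqrt(n))
}
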