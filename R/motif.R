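DNA <- c("A", "C", "G", "T")
DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Position weight matrix
#'
#' @param name motif / factor name.
#' @param probs numeric matrix, one row per position and one column per
#'   letter (A, C, G, T); each row sums to 1.
#' @param pseudocount fraction of background probability mixed into each
#'   column before taking log-odds, so zero entries stay scoreable.
#' @return object of class `pwm` with fields `name`, `width`, `probs`
#'   (regularized), `pseudocount`.
#' @export
pwm <- function(name, probs, pseudocount = 0.001) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4) stop("probs must have 4 columns (A,C,G,T)")
  if (nrow(probs) < 4) stop("PWM width must be >= 4")
  if (any(probs < 0)) stop("negative probabilities")
  sums <- rowSums(probs)
  if (any(abs(sums - 1) > 0.01))
    stop("PWM row ", which(abs(sums - 1) > 0.01)[1], " does not sum to 1")
  probs <- probs / sums
  colnames(probs) <- DNA
  structure(list(name = as.character(name), width = nrow(probs),
                 probs = probs, pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm", x$name, "width", x$width, "\n")
  print(round(x$probs, 3))
  invisible(x)
}

# regularized probabilities: background-proportional pseudocount
reg_probs <- function(pwm, background) {
  p <- sweep(pwm$probs * (1 - 0), 2, 0, `+`)
  p <- (pwm$probs + pwm$pseudocount * rep(background, each = pwm$width)) /
    (1 + pwm$pseudocount)
  p
}

# w x 4 log2 odds matrix against the background
logodds_matrix <- function(pwm, background) {
  p <- reg_probs(pwm, background)
  log2(sweep(p, 2, background, `/`))
}

#' Reverse complement of a PWM
#' @param x a [pwm()].
#' @export
revcomp_pwm <- function(x) {
  p <- x$probs[rev(seq_len(x$width)), rev(seq_len(4)), drop = FALSE]
  colnames(p) <- DNA
  pwm(x$name, p, x$pseudocount)
}

#' Read motifs in MEME minimal format
#'
#' Accepts the minimal motif format: an `ALPHABET= ACGT` line, `MOTIF`
#' headers and `letter-probability matrix` blocks. One [pwm()] per MOTIF
#' block, order preserved.
#'
#' @param path file path.
#' @param pseudocount passed to [pwm()].
#' @return list of [pwm()] objects.
#' @export
read_meme_minimal <- function(path, pseudocount = 0.001) {
  lines <- trimws(readLines(path))
  alph <- grep("^ALPHABET=", lines, value = TRUE)
  if (length(alph)) {
    letters <- gsub("^ALPHABET=\\s*", "", alph[1])
    if (gsub("\\s", "", letters) != "ACGT")
      stop("unsupported alphabet: ", letters)
  }
  motif_idx <- grep("^MOTIF\\b", lines)
  out <- vector("list", length(motif_idx))
  bounds <- c(motif_idx, length(lines) + 1L)
  for (k in seq_along(motif_idx)) {
    name <- strsplit(lines[motif_idx[k]], "\\s+")[[1]][2]
    block <- lines[motif_idx[k]:(bounds[k + 1] - 1L)]
    hdr <- grep("letter-probability matrix", block)
    if (!length(hdr)) stop("MOTIF ", name, ": no letter-probability matrix")
    w <- suppressWarnings(as.integer(
      sub(".*w=\\s*(\\d+).*", "\\1", block[hdr[1]])))
    rows <- block[(hdr[1] + 1):length(block)]
    rows <- rows[nzchar(rows)]
    num <- suppressWarnings(lapply(strsplit(rows, "\\s+"), as.numeric))
    ok <- vapply(num, function(v) length(v) == 4 && !anyNA(v), TRUE)
    if (!is.na(w)) {
      if (sum(cumprod(ok)) < w)
        stop("MOTIF ", name, ": expected ", w, " probability rows")
      num <- num[seq_len(w)]
    } else {
      num <- num[seq_len(sum(cumprod(ok)))]
    }
    out[[k]] <- pwm(name, do.call(rbind, num), pseudocount)
  }
  out
}

#' @rdname read_meme_minimal
#' @param pwms list of [pwm()] objects.
#' @export
write_meme_minimal <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", ""), con)
  for (m in pwms) {
    writeLines(c(paste("MOTIF", m$name),
                 sprintf("letter-probability matrix: alength= 4 w= %d",
                         m$width)), con)
    writeLines(apply(m$probs, 1, function(r)
      paste(sprintf("%.6f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Exact distribution of the PWM log-odds score under the background
#'
#' Computes the distribution of the log-odds score of a random background
#' word of the motif's width. For widths up to `exact_width` the
#' distribution is exact (dynamic programming over per-column score sums
#' with aggregation of equal sums); wider motifs use a discretized grid of
#' `nbins` bins with per-column floor rounding, which makes reported
#' p-values conservative (never smaller than the true tail).
#'
#' @param pwm a [pwm()].
#' @param background length-4 positive probability vector (A,C,G,T).
#' @param nbins grid resolution for the discretized mode.
#' @param exact_width maximum width for the exact mode.
#' @return object of class `score_dist` with ascending `scores`, matching
#'   upper-tail probabilities `tail` (`P(S >= score)`), and the
#'   conservativeness slack `slack` subtracted from query scores.
#' @export
score_to_pvalue <- function(pwm, background = rep(0.25, 4), nbins = 10000,
                            exact_width = 8) {
  background <- check_background(background)
  smat <- logodds_matrix(pwm, background)
  w <- pwm$width
  if (w <= exact_width) {
    sums <- 0
    probs <- 1
    for (j in seq_len(w)) {
      s <- outer(sums, smat[j, ], `+`)
      p <- outer(probs, background, `*`)
      key <- round(as.vector(s), 9)
      agg <- rowsum(as.vector(p), key)
      sums <- as.numeric(rownames(agg))
      probs <- as.vector(agg)
      o <- order(sums)
      sums <- sums[o]; probs <- probs[o]
    }
    tail <- rev(cumsum(rev(probs)))
    return(structure(list(scores = sums, tail = tail, slack = 1e-9,
                          width = w, background = background),
                     class = "score_dist"))
  }
  colmin <- apply(smat, 1, min)
  colmax <- apply(smat, 1, max)
  d <- (sum(colmax) - sum(colmin)) / nbins
  if (d <= 0) d <- 1e-12
  imax <- floor((colmax - colmin) / d)
  dp <- 1
  for (j in seq_len(w)) {
    icol <- floor((smat[j, ] - colmin[j]) / d)
    nxt <- numeric(length(dp) + max(icol))
    for (b in 1:4) {
      idx <- seq_along(dp) + icol[b]
      nxt[idx] <- nxt[idx] + dp * background[b]
    }
    dp <- nxt
  }
  scores <- sum(colmin) + (seq_along(dp) - 1) * d
  keep <- dp > 0
  tail <- rev(cumsum(rev(dp)))
  structure(list(scores = scores[keep], tail = tail[keep],
                 slack = w * d + 1e-9, width = w, background = background),
            class = "score_dist")
}

check_background <- function(background) {
  if (length(background) != 4 || any(background <= 0))
    stop("background must be 4 positive frequencies")
  background / sum(background)
}

#' Upper-tail p-value of observed log-odds scores
#'
#' @param dist a `score_dist` from [score_to_pvalue()].
#' @param s numeric vector of observed scores.
#' @return `P(score >= s)` under the background model (conservatively
#'   rounded for grid-mode distributions).
#' @export
score_pvalue <- function(dist, s) {
  q <- s - dist$slack
  i <- findInterval(q - 1e-12, dist$scores)
  n <- length(dist$scores)
  p <- numeric(length(s))
  inside <- i < n
  p[inside] <- dist$tail[i[inside] + 1L]
  p[!inside] <- dist$tail[n]
  p
}

# smallest score whose reported p-value is < threshold
score_threshold <- function(dist, p_threshold) {
  idx <- which(dist$tail < p_threshold)
  if (!length(idx)) return(Inf)
  dist$scores[min(idx)]
}

#' Table-1 affinity cohort of a match p-value
#'
#' Cohorts bin PWM match p-values into affinity tiers: -5 (`P < 1e-4.5`),
#' -4 (`1e-4.5 <= P < 1e-3.5`), -3 (`1e-3.5 <= P < 1e-2.5`),
#' -2 (`1e-2.5 <= P < 0.04`). Boundary p-values fall into the looser
#' (larger-index) cohort.
#'
#' @param pvalue numeric vector in (0, 0.04).
#' @return integer vector of cohort labels in {-5,-4,-3,-2}.
#' @export
assign_cohort <- function(pvalue) {
  if (any(pvalue <= 0) || any(pvalue >= 0.04))
    stop("cohort p-values must lie in (0, 0.04)")
  breaks <- 10^c(-Inf, -4.5, -3.5, -2.5)
  -5L + findInterval(pvalue, breaks, left.open = FALSE) - 1L
}

seq_to_codes <- function(s) {
  code <- integer(256)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("a")] <- 1L
  code[utf8ToInt("C")] <- 2L; code[utf8ToInt("c")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("g")] <- 3L
  code[utf8ToInt("T")] <- 4L; code[utf8ToInt("t")] <- 4L
  code[utf8ToInt(s)]
}

codes_to_seq <- function(codes) {
  intToUtf8(utf8ToInt("NACGT")[codes + 1L])
}

revcomp_seq <- function(s) {
  chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(s, "")[[1]]),
                                       collapse = ""))
}

# background letter frequencies of a set of sequences (A,C,G,T)
sequence_background <- function(sequences) {
  counts <- numeric(4)
  for (s in sequences) {
    cd <- seq_to_codes(s)
    counts <- counts + tabulate(cd, nbins = 4)
  }
  if (sum(counts) == 0) return(rep(0.25, 4))
  counts / sum(counts)
}

#' Scan sequences for PWM matches with exact p-values
#'
#' Both strands are scored at every offset; windows containing non-ACGT
#' letters are skipped; all matches with `p < p_threshold` are reported
#' (overlapping matches and both strands retained independently).
#'
#' @param sequences named character vector of chromosome sequences (or a
#'   single unnamed string, reported as chromosome "seq").
#' @param pwm a [pwm()].
#' @param p_threshold match p-value threshold (strict).
#' @param background `"genome"` (0-order frequencies estimated from the
#'   scanned sequence), `"uniform"`, or a length-4 frequency vector.
#' @param dist optional precomputed [score_to_pvalue()] distribution.
#' @return data.frame with columns `factor`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `logodds` (bits), `pvalue`, `cohort`.
#' @export
scan_pwm <- function(sequences, pwm, p_threshold = 0.04,
                     background = "genome", dist = NULL) {
  if (p_threshold <= 0 || p_threshold >= 1)
    stop("p_threshold must be in (0,1)")
  if (is.null(names(sequences)))
    names(sequences) <- if (length(sequences) == 1) "seq" else
      paste0("seq", seq_along(sequences))
  bg <- scan_background(sequences, background)
  if (is.null(dist)) dist <- score_to_pvalue(pwm, bg)
  smat_f <- t(logodds_matrix(pwm, bg))          # 4 x w, + strand
  smat_r <- smat_f[4:1, rev(seq_len(pwm$width)), drop = FALSE] # - strand
  thr <- score_threshold(dist, p_threshold)
  res <- list()
  for (ch in names(sequences)) {
    codes <- seq_to_codes(sequences[[ch]])
    for (strand in c("+", "-")) {
      sc <- cpp_pwm_scores(codes, if (strand == "+") smat_f else smat_r)
      hit <- which(!is.na(sc) & sc >= thr - 1e-7)
      if (!length(hit)) next
      p <- score_pvalue(dist, sc[hit])
      keep <- p < p_threshold
      if (!any(keep)) next
      res[[length(res) + 1L]] <- data.frame(
        factor = pwm$name, chrom = ch,
        start = hit[keep] - 1, end = hit[keep] - 1 + pwm$width,
        strand = strand, logodds = sc[hit][keep], pvalue = p[keep],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(factor = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0), logodds = numeric(0),
                      pvalue = numeric(0), cohort = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out$cohort <- NA_integer_
  in_range <- out$pvalue > 0 & out$pvalue < 0.04
  out$cohort[in_range] <- assign_cohort(out$pvalue[in_range])
  out
}

scan_background <- function(sequences, background) {
  if (is.character(background)) {
    background <- match.arg(background, c("genome", "uniform"))
    if (background == "uniform") return(rep(0.25, 4))
    return(sequence_background(sequences))
  }
  check_background(background)
}

# mean per-column Pearson correlation over the best ungapped alignment
# (>= 4 overlapping columns, both orientations)
col_cor_matrix <- function(pa, pb) {
  A <- t(pa); B <- t(pb)                       # 4 x w
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  sa <- sqrt(colSums(A^2)); sb <- sqrt(colSums(B^2))
  M <- crossprod(A, B)
  denom <- outer(sa, sb)
  out <- ifelse(denom > 0, M / denom, 0)
  out
}

best_alignment_stat <- function(Cf, Cc, cols_b) {
  wa <- nrow(Cf); wb <- length(cols_b)
  best <- -Inf
  for (o in -(wb - 4):(wa - 4)) {
    i <- max(1, 1 + o):min(wa, wb + o)
    j <- i - o
    f <- mean(Cf[cbind(i, cols_b[j])])
    r <- mean(Cc[cbind(i, cols_b[wb + 1 - j])])
    best <- max(best, f, r)
  }
  best
}

# statistic for a batch of column permutations at once: perms is an
# n x wb matrix of column orders; returns the per-permutation maximum
# over offsets and orientations
batch_alignment_stats <- function(Cf, Cc, perms) {
  wa <- nrow(Cf); wb <- ncol(perms)
  best <- rep(-Inf, nrow(perms))
  for (o in -(wb - 4):(wa - 4)) {
    i <- max(1, 1 + o):min(wa, wb + o)
    j <- i - o
    jr <- wb + 1 - j
    accf <- 0; accr <- 0
    for (k in seq_along(i)) {
      accf <- accf + Cf[i[k], perms[, j[k]]]
      accr <- accr + Cc[i[k], perms[, jr[k]]]
    }
    best <- pmax(best, accf / length(i), accr / length(i))
  }
  best
}

#' Ungapped similarity statistic between two PWMs
#'
#' Maximum, over all ungapped offsets with at least 4 overlapping columns
#' and both orientations, of the mean per-column Pearson correlation
#' between probability columns.
#'
#' @param pwm_a,pwm_b [pwm()] objects (width >= 4).
#' @export
motif_similarity_stat <- function(pwm_a, pwm_b) {
  pb <- pwm_b$probs
  pb_rc <- revcomp_pwm(pwm_b)$probs
  Cf <- col_cor_matrix(pwm_a$probs, pb)
  # complement columns of b (letter swap only; position reversal handled
  # by index reversal in best_alignment_stat)
  pb_c <- pb[, 4:1, drop = FALSE]; colnames(pb_c) <- DNA
  Cc <- col_cor_matrix(pwm_a$probs, pb_c)
  best_alignment_stat(Cf, Cc, seq_len(pwm_b$width))
}

#' Permutation p-value for PWM similarity
#'
#' Tests whether `pwm_a` is more similar to `pwm_b` than to column-order
#' permutations of `pwm_b`, using [motif_similarity_stat()]. The null is
#' generated by permuting `pwm_b`'s column order `n_perm` times;
#' `p = (1 + #{permuted >= observed}) / (n_perm + 1)`.
#'
#' @param pwm_a,pwm_b [pwm()] objects.
#' @param n_perm number of column permutations.
#' @param seed optional integer seed (local to this call).
#' @export
motif_similarity_pvalue <- function(pwm_a, pwm_b, n_perm = 1000,
                                    seed = NULL) {
  run <- function() {
    pb <- pwm_b$probs
    pb_c <- pb[, 4:1, drop = FALSE]; colnames(pb_c) <- DNA
    Cf <- col_cor_matrix(pwm_a$probs, pb)
    Cc <- col_cor_matrix(pwm_a$probs, pb_c)
    wb <- pwm_b$width
    obs <- best_alignment_stat(Cf, Cc, seq_len(wb))
    perms <- t(vapply(seq_len(n_perm), function(k) sample.int(wb),
                      integer(wb)))
    stats <- batch_alignment_stats(Cf, Cc, perms)
    (1 + sum(stats >= obs - 1e-12)) / (n_perm + 1)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# evaluate f() under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Scrambled-motif null set
#'
#' Generates `n` column-order permutations of a PWM to serve as matched
#' null motifs: each accepted scramble preserves the column multiset
#' (hence total information content) but destroys the recognition
#' sequence. Candidates are rejected if they reproduce the original matrix,
#' duplicate an already accepted scramble, or are significantly similar
#' (`p < alpha` by [motif_similarity_pvalue()]) to any PWM in `others` or
#' any previously accepted scramble.
#'
#' @param pwm a [pwm()].
#' @param n number of scrambles wanted.
#' @param others list of [pwm()] objects the scrambles must not resemble
#'   (typically the genuine PWMs of the other factors).
#' @param alpha similarity rejection level.
#' @param seed optional integer seed (local to this call).
#' @param n_perm permutations per similarity test.
#' @param max_tries candidate budget before giving up.
#' @return list of `n` [pwm()] objects named `<name>_scrambleK`.
#' @export
scramble_pwm <- function(pwm, n = 10, others = list(), alpha = 0.05,
                         seed = NULL, n_perm = 200, max_tries = 100 * n) {
  run <- function() {
    accepted <- list()
    tries <- 0
    while (length(accepted) < n && tries < max_tries) {
      tries <- tries + 1
      perm <- sample.int(pwm$width)
      cand_probs <- pwm$probs[perm, , drop = FALSE]
      if (isTRUE(all.equal(cand_probs, pwm$probs, check.attributes = FALSE)))
        next
      dup <- any(vapply(accepted, function(a)
        isTRUE(all.equal(cand_probs, a$probs, check.attributes = FALSE)),
        TRUE))
      if (dup) next
      cand <- pwm(paste0(pwm$name, "_scramble", length(accepted) + 1),
                  cand_probs, pwm$pseudocount)
      sim_ok <- TRUE
      for (ref in c(others, accepted)) {
        p <- motif_similarity_pvalue(cand, ref, n_perm = n_perm)
        if (p < alpha) { sim_ok <- FALSE; break }
      }
      if (sim_ok) accepted[[length(accepted) + 1]] <- cand
    }
    if (length(accepted) < n)
      stop("scramble_pwm: only ", length(accepted), " of ", n,
           " scrambles accepted after ", tries, " tries")
    accepted
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Fast internal match table: midpoints and affinity cohorts only.
# Cohort boundaries are converted once to score cutoffs on the shared
# score distribution, so no per-match p-value lookup is needed. Returns
# a data.frame(chrom, mid, logodds, cohort) of all matches with
# p < p_max on either strand.
scan_match_mid_cohort <- function(sequences, pwm_obj, dist,
                                  p_max = 0.04, codes_list = NULL) {
  w <- pwm_obj$width
  bg <- dist$background
  smat_f <- t(logodds_matrix(pwm_obj, bg))
  smat_r <- smat_f[4:1, rev(seq_len(w)), drop = FALSE]
  # score cutoffs: s >= cut[k] <=> p < level[k]
  levels <- c(p_max, 10^-2.5, 10^-3.5, 10^-4.5)
  cuts <- vapply(levels, function(l) score_threshold(dist, l), 0)
  res <- list()
  for (ch in names(sequences)) {
    codes <- if (!is.null(codes_list)) codes_list[[ch]] else
      seq_to_codes(sequences[[ch]])
    for (strand in c("+", "-")) {
      sc <- cpp_pwm_scores(codes, if (strand == "+") smat_f else smat_r)
      hit <- which(!is.na(sc) & sc >= cuts[1] - 1e-9)
      if (!length(hit)) next
      s <- sc[hit]
      cohort <- -1L - findInterval(s + 1e-9, sort(cuts))  # -2..-5
      res[[length(res) + 1L]] <- data.frame(
        factor = pwm_obj$name, chrom = ch, mid = hit - 1 + floor(w / 2),
        logodds = s, cohort = cohort, stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(factor = character(0), chrom = character(0),
                      mid = numeric(0), logodds = numeric(0),
                      cohort = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, res)
}
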