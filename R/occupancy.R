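#' Median with notch-style 95% confidence interval
#'
#' CI = median +/- 1.58 * IQR / sqrt(n), with the IQR taken between Tukey
#' hinges (the medians of the lower and upper halves, each including the
#' overall median when n is odd) — the interval drawn by R's notched box
#' plots.
#'
#' @param values numeric vector, n >= 1.
#' @return named numeric vector `c(median, ci_low, ci_high)`.
#' @export
median_ci <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) stop("median_ci: empty input")
  fv <- stats::fivenum(values)
  med <- fv[3]
  half <- 1.58 * (fv[4] - fv[2]) / sqrt(n)
  c(median = med, ci_low = med - half, ci_high = med + half)
}

#' Fraction of ChIP peaks overlapped by accessible chromatin
#'
#' A 1-kb ChIP peak counts as overlapped iff an accessible region overlaps
#' it by at least `min_overlap_bp`, or the peak entirely encompasses some
#' accessible region.
#'
#' @param chip_peaks data.frame with `chrom`, `start`, `end` interval
#'   columns (1-kb peak regions).
#' @param accessible_regions interval data.frame.
#' @param min_overlap_bp overlap threshold in bp.
#' @return list with `fraction`, `n_overlapping`, and the per-peak logical
#'   vector `overlaps`.
#' @export
chip_overlap_fraction <- function(chip_peaks, accessible_regions,
                                  min_overlap_bp = 200) {
  if (nrow(chip_peaks) == 0) stop("chip_overlap_fraction: no peaks")
  ov <- logical(nrow(chip_peaks))
  if (nrow(accessible_regions) > 0) {
    gp <- as_granges(chip_peaks)
    gr <- as_granges(accessible_regions)
    hits <- GenomicRanges::findOverlaps(gp, gr)
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits)
      s <- S4Vectors::subjectHits(hits)
      w <- GenomicRanges::width(GenomicRanges::pintersect(gp[q], gr[s]))
      contained <- accessible_regions$start[s] >= chip_peaks$start[q] &
        accessible_regions$end[s] <= chip_peaks$end[q]
      hit_ok <- w >= min_overlap_bp | contained
      ov[unique(q[hit_ok])] <- TRUE
    }
  }
  list(fraction = mean(ov), n_overlapping = sum(ov), overlaps = ov)
}

#' Hypergeometric base-pair overlap p-value
#'
#' Models the `cover_a_bp` base pairs of feature set A as draws without
#' replacement from a genome of `genome_bp` positions of which
#' `cover_b_bp` belong to feature set B, and returns the upper-tail
#' probability of observing at least `overlap_bp` shared base pairs.
#'
#' @param genome_bp,cover_a_bp,cover_b_bp,overlap_bp non-negative integers.
#' @return `P(X >= overlap_bp)` for `X ~ Hypergeom(genome, cover_b,
#'   cover_a)`.
#' @export
hypergeom_overlap_pvalue <- function(genome_bp, cover_a_bp, cover_b_bp,
                                     overlap_bp) {
  if (cover_a_bp > genome_bp || cover_b_bp > genome_bp)
    stop("coverage exceeds genome size")
  if (overlap_bp > min(cover_a_bp, cover_b_bp))
    stop("overlap exceeds the smaller coverage")
  if (overlap_bp < 0) stop("negative overlap")
  stats::phyper(overlap_bp - 1, m = cover_b_bp, n = genome_bp - cover_b_bp,
                k = cover_a_bp, lower.tail = FALSE)
}

#' Fraction of ranked accessibility peaks covered by factor binding
#'
#' All ChIP peak point locations (any factor) are padded by `pad_bp` on
#' each side and merged once; an accessibility peak is "covered" iff some
#' merged region lies within `near_bp` of its position (distance 0 when
#' overlapping, boundary inclusive). Reports the covered fraction per
#' `cohort_size` cohort down the accessibility rank list.
#'
#' @param ranked_peaks accessibility peaks from [rank_peaks()] (descending
#'   density order).
#' @param chip_positions data.frame with `chrom` and `position` of ChIP
#'   peak point locations, pooled over factors.
#' @param genome a [genome_spec()].
#' @param pad_bp,near_bp,cohort_size see description.
#' @return data.frame with columns `cohort`, `n`, `fraction_covered`,
#'   `partial`.
#' @export
binding_coverage_of_peaks <- function(ranked_peaks, chip_positions, genome,
                                      pad_bp = 500, near_bp = 75,
                                      cohort_size = 1000) {
  n <- nrow(ranked_peaks)
  covered <- logical(n)
  if (nrow(chip_positions) > 0 && n > 0) {
    pts <- intervals(chip_positions$chrom, chip_positions$position,
                     chip_positions$position + 1)
    merged <- merge_intervals(pad(pts, pad_bp, genome), max_gap = 0)
    reach <- merged
    reach$start <- pmax(0, reach$start - near_bp)
    reach$end <- reach$end + near_bp
    qry <- intervals(ranked_peaks$chrom, ranked_peaks$position,
                     ranked_peaks$position + 1)
    hits <- GenomicRanges::findOverlaps(as_granges(qry), as_granges(reach))
    covered[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  if (n == 0)
    return(data.frame(cohort = integer(0), n = integer(0),
                      fraction_covered = numeric(0), partial = logical(0)))
  cohort <- ceiling(seq_len(n) / cohort_size)
  agg <- tapply(covered, cohort, mean)
  sizes <- tabulate(cohort)
  data.frame(cohort = as.integer(names(agg)), n = sizes,
             fraction_covered = as.numeric(agg),
             partial = sizes < cohort_size, row.names = NULL)
}

#' ChIP score surface from 1-kb peaks
#'
#' Peak scores are attributed uniformly across each peak's interval;
#' positions outside every peak take `floor_score` (by default the
#' minimum reported peak score). Used to answer "maximum ChIP score within
#' a window" queries against peak-list data.
#'
#' @param chip_peaks data.frame with `chrom`, `start`, `end`, `score`.
#' @param floor_score background score outside peaks.
#' @return object of class `chip_surface`.
#' @export
chip_score_surface <- function(chip_peaks, floor_score = NULL) {
  if (is.null(floor_score))
    floor_score <- if (nrow(chip_peaks)) min(chip_peaks$score) else 0
  structure(list(gr = if (nrow(chip_peaks)) as_granges(chip_peaks) else NULL,
                 scores = chip_peaks$score, floor = floor_score),
            class = "chip_surface")
}

#' Maximum ChIP score within a window of each position
#'
#' @param surface a [chip_score_surface()].
#' @param chrom,position vectors of 0-based query positions.
#' @param flank_bp half-window; positions within `flank_bp` (inclusive) of
#'   the query contribute.
#' @export
max_chip_score <- function(surface, chrom, position, flank_bp) {
  out <- rep(surface$floor, length(position))
  if (is.null(surface$gr) || length(position) == 0) return(out)
  qry <- GenomicRanges::GRanges(chrom, IRanges::IRanges(
    start = pmax(1, position - flank_bp + 1), end = position + flank_bp + 1))
  hits <- GenomicRanges::findOverlaps(qry, surface$gr)
  if (!length(hits)) return(out)
  gm <- cpp_group_max(S4Vectors::queryHits(hits),
                      surface$scores[S4Vectors::subjectHits(hits)],
                      length(position))
  hitq <- !is.na(gm)
  out[hitq] <- pmax(gm[hitq], surface$floor)
  out
}

#' Rank-cohort accessibility of ChIP peaks
#'
#' Ranks ChIP peaks by score, and per non-overlapping cohort of
#' `cohort_size` peaks reports the median (with notch 95% CI) of the
#' maximum DNase tag density within `window_bp` of each peak position for
#' every supplied stage track, plus the fraction of peaks overlapped by
#' accessible regions under the >= 200 bp / encompassment rule.
#'
#' @param chip_peaks data.frame with `chrom`, `peak_position`, `start`,
#'   `end`, `score` (typically the 25% FDR peak list of one factor).
#' @param tracks_by_stage named list of [tag_track()] objects.
#' @param accessible_regions regions used for the overlap fraction
#'   (typically the earliest stage).
#' @param cohort_size,window_bp see description.
#' @return data.frame with one row per (stage, cohort): `stage`, `cohort`,
#'   `n`, `median`, `ci_low`, `ci_high`, `fraction_overlapping`, `partial`.
#' @export
chip_rank_accessibility_curves <- function(chip_peaks, tracks_by_stage,
                                           accessible_regions,
                                           cohort_size = 200,
                                           window_bp = 500) {
  if (nrow(chip_peaks) == 0) stop("no ChIP peaks")
  ord <- order(-chip_peaks$score, chip_peaks$chrom, chip_peaks$peak_position)
  pk <- chip_peaks[ord, , drop = FALSE]
  n <- nrow(pk)
  if (n < cohort_size)
    warning("fewer than ", cohort_size, " peaks: single partial cohort")
  cohort <- ceiling(seq_len(n) / cohort_size)
  ov <- chip_overlap_fraction(pk, accessible_regions)$overlaps
  out <- list()
  for (stage in names(tracks_by_stage)) {
    dens <- max_track_density(tracks_by_stage[[stage]], pk$chrom,
                              pk$peak_position, window_bp)
    for (co in unique(cohort)) {
      idx <- which(cohort == co)
      mc <- median_ci(dens[idx])
      out[[length(out) + 1L]] <- data.frame(
        stage = stage, cohort = co, n = length(idx),
        median = mc[["median"]], ci_low = mc[["ci_low"]],
        ci_high = mc[["ci_high"]],
        fraction_overlapping = mean(ov[idx]),
        partial = length(idx) < cohort_size, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Maximum binned tag density near positions
#'
#' @param track a [tag_track()].
#' @param chrom,position query vectors (0-based bp).
#' @param flank_bp half-window in bp; all bins overlapping
#'   `[position - flank_bp, position + flank_bp]` contribute.
#' @return numeric vector of per-query maxima (tags per bin).
#' @export
max_track_density <- function(track, chrom, position, flank_bp) {
  bin <- track$bin_size
  out <- numeric(length(position))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    lo <- floor((position[idx] - flank_bp) / bin) + 1
    hi <- floor((position[idx] + flank_bp) / bin) + 1
    out[idx] <- cpp_window_max(track$counts[[ch]], as.integer(lo),
                               as.integer(hi))
  }
  out
}

#' Mean binned tag density near positions
#'
#' @inheritParams max_track_density
#' @return numeric vector of per-query means (tags per bin) over all bins
#'   overlapping `[position - flank_bp, position + flank_bp]`.
#' @export
mean_track_density <- function(track, chrom, position, flank_bp) {
  bin <- track$bin_size
  out <- numeric(length(position))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    cts <- track$counts[[ch]]
    cs <- c(0, cumsum(cts))
    lo <- pmax(1, floor((position[idx] - flank_bp) / bin) + 1)
    hi <- pmin(length(cts), floor((position[idx] + flank_bp) / bin) + 1)
    out[idx] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  out
}

#' Affinity-cohort occupancy table
#'
#' Classifies PWM matches by chromatin compartment (match midpoint inside
#' a 5% FDR accessible region or not) and affinity cohort, and summarises
#' the maximum ChIP score within `window_bp` of each match: n, median and
#' notch 95% CI per (compartment, motif kind, cohort) cell. Scrambled
#' matches are pooled over the whole scramble set before the median is
#' taken.
#'
#' @param matches_genuine matches of one factor's genuine PWM (from
#'   [scan_pwm()], with `cohort` filled; a `mid` column may replace
#'   `start`/`end`).
#' @param matches_scrambled pooled matches of the factor's scrambled PWM
#'   set (may have zero rows).
#' @param accessible_regions interval data.frame.
#' @param chip_surface a [chip_score_surface()] of the factor's ChIP
#'   peaks.
#' @param window_bp half-window for the score query.
#' @return data.frame with `factor`, `compartment`, `motif_kind`,
#'   `cohort`, `n`, `median`, `ci_low`, `ci_high` (NA medians for empty
#'   cells).
#' @export
affinity_cohort_analysis <- function(matches_genuine, matches_scrambled,
                                     accessible_regions, chip_surface,
                                     window_bp = 250) {
  fac <- if (nrow(matches_genuine)) matches_genuine$factor[1] else NA_character_
  summarise <- function(matches, kind) {
    cells <- expand.grid(compartment = c("accessible", "closed"),
                         cohort = c(-5L, -4L, -3L, -2L),
                         stringsAsFactors = FALSE)
    cells$factor <- fac
    cells$motif_kind <- kind
    cells$n <- 0L
    cells$median <- NA_real_
    cells$ci_low <- NA_real_
    cells$ci_high <- NA_real_
    if (nrow(matches) == 0)
      return(cells[, c("factor", "compartment", "motif_kind", "cohort",
                       "n", "median", "ci_low", "ci_high")])
    mid <- if ("mid" %in% names(matches)) matches$mid else
      floor((matches$start + matches$end) / 2)
    comp <- compartment_of(matches$chrom, mid, accessible_regions)
    val <- max_chip_score(chip_surface, matches$chrom, mid, window_bp)
    key <- (comp == "accessible") * 10L + (matches$cohort + 6L)
    spl <- split(val, key)
    for (i in seq_len(nrow(cells))) {
      v <- spl[[as.character((cells$compartment[i] == "accessible") * 10L +
                               (cells$cohort[i] + 6L))]]
      if (is.null(v)) next
      cells$n[i] <- length(v)
      mc <- median_ci(v)
      cells$median[i] <- mc[["median"]]
      cells$ci_low[i] <- mc[["ci_low"]]
      cells$ci_high[i] <- mc[["ci_high"]]
    }
    cells[, c("factor", "compartment", "motif_kind", "cohort", "n",
              "median", "ci_low", "ci_high")]
  }
  rbind(summarise(matches_genuine, "genuine"),
        summarise(matches_scrambled, "scrambled"))
}

compartment_of <- function(chrom, position, accessible_regions) {
  comp <- rep("closed", length(position))
  if (nrow(accessible_regions) == 0 || length(position) == 0) return(comp)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    rg <- accessible_regions[accessible_regions$chrom == ch, , drop = FALSE]
    if (nrow(rg) == 0) next
    o <- order(rg$start)
    st <- rg$start[o]; en <- rg$end[o]
    if (any(en[-length(en)] > st[-1])) {
      # overlapping regions: fall back to interval overlap
      hits <- GenomicRanges::findOverlaps(
        GenomicRanges::GRanges(ch, IRanges::IRanges(position[idx] + 1,
                                                    width = 1)),
        as_granges(rg))
      comp[idx[unique(S4Vectors::queryHits(hits))]] <- "accessible"
    } else {
      j <- findInterval(position[idx], st)
      inside <- j >= 1 & position[idx] < en[pmax(j, 1)]
      comp[idx[inside]] <- "accessible"
    }
  }
  comp
}

#' Accessibility-rank occupancy and site-density matrices
#'
#' For each accessibility peak (ranked by density) and factor, records the
#' maximum ChIP score within `near_bp` of the peak and the number of
#' genuine PWM matches at `p < p_match` whose midpoints lie within
#' `near_bp`. Pearson correlations against peak density are computed over
#' all peaks; cohort rows (median ChIP score, summed site counts per
#' `cohort_size` peaks) are scaled per row for heat-map style display.
#'
#' @param ranked_peaks accessibility peaks from [rank_peaks()].
#' @param chip_surfaces_by_factor named list of [chip_score_surface()].
#' @param matches_by_factor named list of match data.frames (same names).
#' @param near_bp,p_match,cohort_size see description.
#' @param row_scale `"median"` (divide each row by its median; count rows
#'   by their maximum when the median is 0) or `"zscore"`.
#' @return list with `correlations` (factor, r_chip, r_count, n),
#'   `chip_matrix`, `count_matrix` (factors x cohorts, scaled),
#'   `density` (per-cohort median density, scaled), `n_cohorts`.
#' @export
accessibility_rank_matrix <- function(ranked_peaks, chip_surfaces_by_factor,
                                      matches_by_factor, near_bp = 75,
                                      p_match = 0.003, cohort_size = 200,
                                      row_scale = c("median", "zscore")) {
  row_scale <- match.arg(row_scale)
  factors <- names(chip_surfaces_by_factor)
  n <- nrow(ranked_peaks)
  cohort <- ceiling(seq_len(n) / cohort_size)
  full <- which(tabulate(cohort) == cohort_size)
  chipm <- matrix(NA_real_, length(factors), length(full),
                  dimnames = list(factors, NULL))
  cntm <- chipm
  cors <- data.frame(factor = factors, r_chip = NA_real_,
                     r_count = NA_real_, n = n, stringsAsFactors = FALSE)
  dens <- ranked_peaks$density
  for (f in seq_along(factors)) {
    fac <- factors[f]
    chip_val <- max_chip_score(chip_surfaces_by_factor[[fac]],
                               ranked_peaks$chrom, ranked_peaks$position,
                               near_bp)
    mt <- matches_by_factor[[fac]]
    if ("pvalue" %in% names(mt))
      mt <- mt[mt$pvalue < p_match, , drop = FALSE]
    cnt <- count_near(ranked_peaks$chrom, ranked_peaks$position, mt, near_bp)
    cors$r_chip[f] <- stats::cor(chip_val, dens)
    cors$r_count[f] <- if (nrow(mt) == 0) NA_real_ else
      suppressWarnings(stats::cor(cnt, dens))
    for (k in seq_along(full)) {
      idx <- which(cohort == full[k])
      chipm[f, k] <- stats::median(chip_val[idx])
      cntm[f, k] <- sum(cnt[idx])
    }
  }
  dens_row <- vapply(seq_along(full), function(k)
    stats::median(dens[cohort == full[k]]), 0)
  list(correlations = cors,
       chip_matrix = scale_rows(chipm, row_scale),
       count_matrix = scale_rows(cntm, row_scale),
       density = scale_rows(matrix(dens_row, 1), row_scale)[1, ],
       n_cohorts = length(full))
}

count_near <- function(chrom, position, matches, near_bp) {
  cnt <- numeric(length(position))
  if (nrow(matches) == 0) return(cnt)
  mid <- if ("mid" %in% names(matches)) matches$mid else
    floor((matches$start + matches$end) / 2)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    m <- sort(mid[matches$chrom == ch])
    if (!length(m)) next
    cnt[idx] <- findInterval(position[idx] + near_bp, m) -
      findInterval(position[idx] - near_bp - 1e-9, m)
  }
  cnt
}

scale_rows <- function(m, how) {
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    if (how == "zscore") {
      s <- stats::sd(v)
      m[i, ] <- if (is.na(s) || s == 0) v * 0 else (v - mean(v)) / s
    } else {
      d <- stats::median(v)
      if (!is.na(d) && d == 0) d <- max(v)
      m[i, ] <- if (is.na(d) || d == 0) v else v / d
    }
  }
  m
}
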