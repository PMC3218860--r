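#' Most highly bound genomic regions
#'
#' Takes the top `n` ChIP peaks by score (ties broken by leftmost
#' coordinate) and returns the 1-kb regions `peak_position +/- flank_bp`.
#'
#' @param chip_peaks ChIP peak data.frame (`chrom`, `peak_position`,
#'   `score`).
#' @param n number of regions.
#' @param flank_bp half-width of the returned regions.
#' @param genome optional [genome_spec()] for end clipping.
#' @return interval data.frame with `score` carried over, in descending
#'   score order.
#' @export
top_bound_regions <- function(chip_peaks, n = 400, flank_bp = 500,
                              genome = NULL) {
  if (nrow(chip_peaks) < n) {
    warning("only ", nrow(chip_peaks), " peaks available (requested ", n,
            ")")
    n <- nrow(chip_peaks)
  }
  ord <- order(-chip_peaks$score, chip_peaks$chrom,
               chip_peaks$peak_position)
  top <- chip_peaks[ord[seq_len(n)], , drop = FALSE]
  out <- intervals(top$chrom, pmax(0, top$peak_position - flank_bp),
                   top$peak_position + flank_bp, score = top$score)
  if (!is.null(genome))
    out$end <- pmin(out$end, chrom_length(genome, out$chrom))
  out
}

#' Correlation of between-stage occupancy and accessibility ratios
#'
#' Per region: the ChIP ratio is the maximum peak score overlapping the
#' region at stage X over the same at stage Y (regions with no overlapping
#' peak at a stage take `chip_floor`); the DNase ratio is the region's
#' cleavage density (total tags in the region by default, or the maximum
#' window density) at X over Y, with `pseudocount` tags added to both.
#' Returns the Pearson correlation of the two ratio vectors over regions,
#' plus the per-region records.
#'
#' @param regions 1-kb regions from [top_bound_regions()] at stage X.
#' @param chip_x,chip_y ChIP peak data.frames for the two stages.
#' @param track_x,track_y [tag_track()] objects for the two stages.
#' @param pseudocount tags added to both DNase densities (guards zero
#'   denominators).
#' @param chip_floor score assigned when no peak overlaps at a stage
#'   (default: the stage's minimum reported score).
#' @param log_scale correlate log ratios instead of natural-scale ratios.
#' @param density_stat region DNase density: `"total"` tags in the
#'   region (the region's cleavage density) or `"max"` window density.
#' @return list with `r` (Pearson), `n`, and `records` (data.frame of
#'   per-region chip_ratio, dnase_ratio).
#' @export
stage_ratio_correlation <- function(regions, chip_x, chip_y, track_x,
                                    track_y, pseudocount = 1,
                                    chip_floor = NULL, log_scale = FALSE,
                                    density_stat = c("total", "max")) {
  density_stat <- match.arg(density_stat)
  if (nrow(regions) < 3) stop("need at least 3 regions")
  score_at <- function(chip) {
    floor_sc <- if (is.null(chip_floor)) min(chip$score) else chip_floor
    surf <- chip_score_surface(chip, floor_score = floor_sc)
    mid <- floor((regions$start + regions$end) / 2)
    max_chip_score(surf, regions$chrom, mid,
                   flank_bp = floor((regions$end - regions$start) / 2))
  }
  dens_at <- function(track) {
    mid <- floor((regions$start + regions$end) / 2)
    flank <- floor((regions$end - regions$start) / 2)
    if (density_stat == "max")
      max_track_density(track, regions$chrom, mid, flank)
    else mean_track_density(track, regions$chrom, mid, flank) *
      (2 * flank / track$bin_size)
  }
  sx <- score_at(chip_x); sy <- score_at(chip_y)
  dx <- dens_at(track_x); dy <- dens_at(track_y)
  if (any(sy == 0) || any(dy + pseudocount == 0))
    stop("zero denominator in stage ratios")
  rec <- data.frame(chrom = regions$chrom, start = regions$start,
                    end = regions$end,
                    chip_ratio = sx / sy,
                    dnase_ratio = (dx + pseudocount) / (dy + pseudocount),
                    stringsAsFactors = FALSE)
  x <- rec$chip_ratio; y <- rec$dnase_ratio
  if (log_scale) { x <- log(x); y <- log(y) }
  list(r = stats::cor(x, y), n = nrow(rec), records = rec)
}

#' Correlation of replicate ChIP scores
#'
#' For each 25% FDR peak of replicate A, records the maximum score of A
#' and of B within `window_bp`, and returns their Pearson correlation.
#'
#' @param chip_a,chip_b ChIP peak data.frames (replicates).
#' @param window_bp half-window around each peak of A.
#' @export
replicate_score_correlation <- function(chip_a, chip_b, window_bp = 500) {
  peaks <- chip_fdr_subset(chip_a, "25%")
  if (nrow(peaks) == 0) stop("no 25% FDR peaks in replicate A")
  sa <- max_chip_score(chip_score_surface(chip_a), peaks$chrom,
                       peaks$peak_position, window_bp)
  sb <- max_chip_score(chip_score_surface(chip_b), peaks$chrom,
                       peaks$peak_position, window_bp)
  stats::cor(sa, sb)
}
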