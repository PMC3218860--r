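#' Call accessible regions against a local background
#'
#' Slides a `window_bp` window (step = bin size) along each chromosome,
#' tests each window's tag sum against a Poisson rate estimated from the
#' surrounding `background_bp` of signal (centered on the window, clipped
#' at chromosome ends, including the window itself by default), adjusts
#' genome-wide with Benjamini-Hochberg and merges significant windows
#' closer than `merge_gap` into regions.
#'
#' @param track a [tag_track()].
#' @param fdr target false discovery rate in (0,1).
#' @param window_bp test window width; rounded to the nearest whole number
#'   of track bins (150 bp becomes 160 bp on a 20-bp track).
#' @param background_bp local background width.
#' @param merge_gap maximum gap (bp) bridged when merging windows.
#' @param include_self logical; keep the test window inside its own
#'   background (conservative for narrow peaks).
#' @return interval data.frame with columns `chrom`, `start`, `end`,
#'   `name`, `score` (max constituent window tag sum), `pvalue` (min
#'   window p), `qvalue` (min window BH q).
#' @export
call_accessible_regions <- function(track, fdr = 0.05, window_bp = 150,
                                    background_bp = 50000, merge_gap = 50,
                                    include_self = TRUE) {
  if (fdr <= 0 || fdr >= 1) stop("fdr must be in (0,1)")
  bin <- track$bin_size
  wb <- max(1L, as.integer(round(window_bp / bin)))
  window_bp <- wb * bin
  tests <- list()
  for (ch in names(track$counts)) {
    cts <- track$counts[[ch]]
    nb <- length(cts)
    if (nb < wb) next
    cs <- c(0, cumsum(cts))
    k <- seq_len(nb - wb + 1)              # window start bins
    wsum <- cs[k + wb] - cs[k]
    ctr <- k + (wb - 1) / 2                # center, bin units
    half <- background_bp / bin / 2
    lo <- pmax(1, ceiling(ctr - half))
    hi <- pmin(nb, floor(ctr + half))
    bgsum <- cs[hi + 1] - cs[lo]
    bgbp <- (hi - lo + 1) * bin
    if (!include_self) {
      bgsum <- bgsum - wsum
      bgbp <- bgbp - window_bp
    }
    lambda <- bgsum / bgbp * window_bp
    p <- stats::ppois(ceiling(wsum) - 1, lambda, lower.tail = FALSE)
    tests[[ch]] <- data.frame(chrom = ch, start = (k - 1) * bin,
                              end = pmin((k - 1) * bin + window_bp,
                                         chrom_length(track$genome, ch)),
                              sum = wsum, pvalue = p,
                              stringsAsFactors = FALSE)
  }
  if (!length(tests)) return(empty_region_set())
  tab <- do.call(rbind, tests)
  tab$qvalue <- stats::p.adjust(tab$pvalue, method = "BH")
  sig <- tab[tab$qvalue <= fdr, , drop = FALSE]
  if (nrow(sig) == 0) return(empty_region_set())
  merged <- merge_intervals(intervals(sig$chrom, sig$start, sig$end),
                            max_gap = merge_gap)
  hits <- GenomicRanges::findOverlaps(as_granges(sig), as_granges(merged))
  qh <- S4Vectors::subjectHits(hits)
  sh <- S4Vectors::queryHits(hits)
  merged$score <- as.numeric(tapply(sig$sum[sh], qh, max)[as.character(
    seq_len(nrow(merged)))])
  merged$pvalue <- as.numeric(tapply(sig$pvalue[sh], qh, min)[as.character(
    seq_len(nrow(merged)))])
  merged$qvalue <- as.numeric(tapply(sig$qvalue[sh], qh, min)[as.character(
    seq_len(nrow(merged)))])
  merged$name <- sprintf("region_%d", seq_len(nrow(merged)))
  merged
}

empty_region_set <- function() {
  out <- empty_intervals()
  out$pvalue <- numeric(0)
  out$qvalue <- numeric(0)
  out
}

#' Replicate-concordant accessible regions
#'
#' Retains regions of replicate 1 that overlap (by at least 1 bp) some
#' region of replicate 2, intersecting coordinates; scores and p-values
#' are carried over from replicate 1. A replicate-1 region overlapping
#' several replicate-2 regions yields one row per intersected fragment.
#'
#' @param regions_rep1,regions_rep2 region sets from
#'   [call_accessible_regions()].
#' @export
concordant_regions <- function(regions_rep1, regions_rep2) {
  if (nrow(regions_rep1) == 0 || nrow(regions_rep2) == 0)
    return(regions_rep1[0, , drop = FALSE])
  g1 <- as_granges(regions_rep1)
  g2 <- as_granges(regions_rep2)
  hits <- GenomicRanges::findOverlaps(g1, g2, minoverlap = 1L)
  if (length(hits) == 0) return(regions_rep1[0, , drop = FALSE])
  q <- S4Vectors::queryHits(hits)
  inter <- GenomicRanges::pintersect(g1[q], g2[S4Vectors::subjectHits(hits)])
  out <- regions_rep1[q, , drop = FALSE]
  out$start <- GenomicRanges::start(inter) - 1
  out$end <- as.numeric(GenomicRanges::end(inter))
  rownames(out) <- NULL
  out
}

# windowed max/min of v over +/- r positions (index units)
windowed_extreme <- function(v, r, op) {
  out <- v
  m <- length(v)
  pad <- if (identical(op, pmax)) -Inf else Inf
  for (s in seq_len(min(r, m - 1))) {
    left <- c(rep(pad, s), v[seq_len(m - s)])
    right <- c(v[-seq_len(s)], rep(pad, s))
    out <- op(out, left, right)
  }
  out
}

#' Detect local accessibility maxima within regions
#'
#' Tag densities are taken in `window_bp` sliding windows (step = bin
#' size) inside each region; a window is a peak iff its density is >= all
#' windows whose centers lie within `near_bp` of its own and strictly
#' greater than at least one of them. Ties are broken leftmost; every
#' region yields at least one peak (falling back to the leftmost maximum
#' bin for flat or very short regions).
#'
#' @param track the [tag_track()] the regions were called on.
#' @param regions interval data.frame of accessible regions.
#' @param window_bp density window (default one 20-bp bin).
#' @param near_bp local-maximum radius in bp.
#' @return data.frame with columns `chrom`, `position` (window center
#'   bp), `density` (tags per window), `region` (region row index).
#' @export
detect_peaks <- function(track, regions, window_bp = 20, near_bp = 75) {
  bin <- track$bin_size
  if (window_bp %% bin != 0)
    stop("window_bp must be a multiple of the bin size")
  wb <- window_bp %/% bin
  r <- floor(near_bp / bin)
  out <- list()
  for (i in seq_len(nrow(regions))) {
    ch <- regions$chrom[i]
    cts <- track$counts[[ch]]
    b0 <- floor(regions$start[i] / bin) + 1
    b1 <- min(ceiling(regions$end[i] / bin), length(cts))
    v <- cts[b0:b1]
    m <- length(v)
    if (m >= wb && wb > 1) {
      cs <- c(0, cumsum(v))
      v <- cs[(wb + 1):(m + 1)] - cs[seq_len(m - wb + 1)]
      m <- length(v)
    }
    if (m == 1) {
      peaks <- 1L
    } else {
      wmax <- windowed_extreme(v, r, pmax)
      wmin <- windowed_extreme(v, r, pmin)
      cand <- which(v >= wmax & wmin < v)
      kept <- integer(0)
      for (k in cand) {
        if (!any(kept >= k - r & v[kept] == v[k])) kept <- c(kept, k)
      }
      peaks <- kept
      if (!length(peaks)) peaks <- which.max(v)[1]
    }
    pos <- (b0 - 1 + peaks - 1) * bin + floor(wb * bin / 2)
    out[[i]] <- data.frame(chrom = ch, position = pos, density = v[peaks],
                           region = i, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(0), position = numeric(0),
                      density = numeric(0), region = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank accessibility peaks by density
#'
#' Descending by density; ties broken by (chrom, position) ascending.
#'
#' @param peaks data.frame from [detect_peaks()].
#' @export
rank_peaks <- function(peaks) {
  if (nrow(peaks) == 0) return(peaks)
  out <- peaks[order(-peaks$density, peaks$chrom, peaks$position), ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}
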