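#' Read a BED file
#'
#' Parses BED3/BED5 (tab-separated, 0-based half-open). Column 4 becomes
#' `name`, column 5 `score`; further columns are ignored. Malformed lines
#' raise an error naming the offending line number.
#'
#' @param path file path.
#' @return An interval data.frame (see [intervals()]); input order preserved.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_intervals())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", bad[1], ": non-numeric coordinates")
  bad <- which(start >= end)
  if (length(bad))
    stop("malformed BED line ", bad[1], ": start >= end")
  name <- ifelse(nf >= 4, vapply(fields, function(f)
    if (length(f) >= 4) f[[4]] else NA_character_, ""), NA_character_)
  score <- suppressWarnings(as.numeric(ifelse(
    nf >= 5,
    vapply(fields, function(f) if (length(f) >= 5) f[[5]] else NA_character_, ""),
    NA_character_)))
  intervals(chrom, start, end, name = name, score = score)
}

#' Write intervals as BED
#'
#' Writes BED3 when neither name nor score is present, BED5 otherwise
#' (missing names become "."; missing scores 0 only if some scores exist).
#' `read_bed(write_bed(x))` round-trips coordinates, names and scores.
#'
#' @param x interval data.frame.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  if (nrow(x) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  has_name <- !all(is.na(x$name))
  has_score <- !all(is.na(x$score))
  cols <- list(x$chrom, format_bp(x$start), format_bp(x$end))
  if (has_name || has_score)
    cols <- c(cols, list(ifelse(is.na(x$name), ".", x$name)))
  if (has_score)
    cols <- c(cols, list(format_num(x$score)))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)
format_num <- function(x) {
  out <- formatC(x, format = "g", digits = 15)
  out[is.na(x)] <- "NA"
  trimws(out)
}

#' Tag-density track
#'
#' A `tag_track` holds per-chromosome binned tag counts: the DNase signal.
#' Bin `i` (1-based) of a chromosome covers base pairs
#' `[(i-1)*bin_size, i*bin_size)`; the last bin may be truncated by the
#' chromosome end.
#'
#' @param genome a [genome_spec()].
#' @param bin_size bin width in bp.
#' @param counts named list (one numeric vector per chromosome) of
#'   non-negative per-bin counts; defaults to all-zero.
#' @return object of class `tag_track`.
#' @export
tag_track <- function(genome, bin_size, counts = NULL) {
  nbins <- ceiling(unclass(genome) / bin_size)
  if (is.null(counts))
    counts <- lapply(nbins, function(n) numeric(n))
  if (!identical(sort(names(counts)), sort(names(genome))))
    stop("counts must have one element per chromosome")
  for (ch in names(genome)) {
    if (length(counts[[ch]]) != nbins[[ch]])
      stop("chromosome ", ch, ": expected ", nbins[[ch]], " bins, got ",
           length(counts[[ch]]))
    if (any(counts[[ch]] < 0)) stop("negative counts on ", ch)
  }
  structure(list(genome = genome, bin_size = bin_size,
                 counts = counts[names(genome)]),
            class = "tag_track")
}

#' @export
print.tag_track <- function(x, ...) {
  cat("tag_track:", length(x$counts), "chromosome(s), bin", x$bin_size,
      "bp, total tags", format(sum(unlist(x$counts)), big.mark = ","), "\n")
  invisible(x)
}

#' Read a bedGraph file into a binned track
#'
#' Values are interpreted as per-bp tag density; each record contributes
#' `value * overlap_bp` to every bin it overlaps (bp-weighted re-binning).
#' Positions not covered by any record are 0.
#'
#' @param path bedGraph path (4 columns, no track lines required).
#' @param genome a [genome_spec()].
#' @param bin_size bin width in bp.
#' @return a [tag_track()].
#' @export
read_bedgraph_as_track <- function(path, genome, bin_size) {
  trk <- tag_track(genome, bin_size)
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) return(trk)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "value"),
                           colClasses = c("character", "numeric", "numeric",
                                          "numeric"))
  if (nrow(tab) == 0) return(trk)
  validate_intervals(tab)
  over <- tab$end > chrom_length(genome, tab$chrom)
  if (any(over))
    stop("bedGraph record beyond chromosome end at line ", which(over)[1])
  for (ch in unique(tab$chrom)) {
    rec <- tab[tab$chrom == ch, ]
    acc <- trk$counts[[ch]]
    for (i in seq_len(nrow(rec))) {
      b0 <- floor(rec$start[i] / bin_size) + 1
      b1 <- ceiling(rec$end[i] / bin_size)
      bins <- b0:b1
      lo <- pmax((bins - 1) * bin_size, rec$start[i])
      hi <- pmin(bins * bin_size, rec$end[i])
      acc[bins] <- acc[bins] + rec$value[i] * (hi - lo)
    }
    trk$counts[[ch]] <- acc
  }
  trk
}

#' Write a track as bedGraph
#'
#' Inverse of [read_bedgraph_as_track()] at matching bin boundaries: each
#' bin is emitted as one record with value = count / bin width (per-bp
#' density); zero bins are skipped.
#'
#' @param track a [tag_track()].
#' @param path output path.
#' @export
write_track_as_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$counts)) {
    cts <- track$counts[[ch]]
    nz <- which(cts != 0)
    if (!length(nz)) next
    start <- (nz - 1) * track$bin_size
    end <- pmin(nz * track$bin_size, chrom_length(track$genome, ch))
    writeLines(paste(ch, format_bp(start), format_bp(end),
                     format_num(cts[nz] / (end - start)), sep = "\t"), con)
  }
  invisible(path)
}

#' Merge intervals closer than a gap
#'
#' Sorts and unions intervals, additionally bridging gaps of at most
#' `max_gap` bp (a gap exactly equal to `max_gap` merges).
#'
#' @param x interval data.frame.
#' @param max_gap non-negative gap tolerance in bp.
#' @return sorted, non-overlapping interval data.frame covering the union
#'   of `x` plus bridged gaps.
#' @export
merge_intervals <- function(x, max_gap = 0) {
  if (max_gap < 0) stop("max_gap must be >= 0")
  validate_intervals(x)
  if (nrow(x) == 0) return(empty_intervals())
  gr <- GenomicRanges::reduce(as_granges(x), min.gapwidth = max_gap + 1)
  gr <- GenomicRanges::sort(gr)
  granges_to_intervals(gr)
}

#' Base pairs of overlap between two intervals
#'
#' @param a,b single intervals (one-row data.frames or list-like with
#'   `chrom`, `start`, `end`). Vectorized elementwise over equal lengths.
#' @return `max(0, min(ends) - max(starts))` when on the same chromosome,
#'   otherwise 0.
#' @export
overlap_bp <- function(a, b) {
  ifelse(a$chrom == b$chrom,
         pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start)),
         0)
}

#' Pad intervals by a flank, clipped to the chromosome
#'
#' @param x interval data.frame.
#' @param flank_bp non-negative flank in bp added to both ends.
#' @param genome a [genome_spec()] used for clipping.
#' @export
pad <- function(x, flank_bp, genome) {
  if (flank_bp < 0) stop("flank_bp must be >= 0")
  validate_intervals(x)
  if (nrow(x) == 0) return(x)
  x$start <- pmax(0, x$start - flank_bp)
  x$end <- pmin(chrom_length(genome, x$chrom), x$end + flank_bp)
  x
}

#' Total base-pair coverage of an interval set
#'
#' @param x interval data.frame (overlaps counted once).
#' @return total covered bp.
#' @export
coverage_bp <- function(x) {
  if (nrow(x) == 0) return(0)
  m <- merge_intervals(x, max_gap = 0)
  sum(m$end - m$start)
}
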