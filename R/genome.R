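#' Genome specification
#'
#' A `genome_spec` is an ordered set of chromosome names and lengths. It is
#' the coordinate frame every other container (intervals, tag tracks,
#' sequences) is validated against.
#'
#' @param chroms character vector of chromosome names (unique).
#' @param lengths integer vector of chromosome lengths in base pairs (> 0).
#' @return An object of class `genome_spec`: a named integer vector of
#'   lengths, ordered as given.
#' @examples
#' genome_spec("chr2L", 2e6)
#' @export
genome_spec <- function(chroms, lengths) {
  chroms <- as.character(chroms)
  lengths <- as.numeric(lengths)
  if (length(chroms) != length(lengths))
    stop("chroms and lengths must have equal length")
  if (anyDuplicated(chroms)) stop("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths <= 0) ||
      any(lengths != floor(lengths)))
    stop("chromosome lengths must be positive integers")
  structure(stats::setNames(lengths, chroms), class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("genome_spec:", length(x), "chromosome(s),",
      format(sum(x), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Read a two-column chrom.sizes file
#'
#' @param path path to a tab-separated file with columns name, length.
#' @return A [genome_spec()].
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "numeric"))
  genome_spec(tab[[1]], tab[[2]])
}

#' @rdname read_chrom_sizes
#' @param genome a `genome_spec`.
#' @export
write_chrom_sizes <- function(genome, path) {
  utils::write.table(data.frame(names(genome), as.integer(genome)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

chrom_length <- function(genome, chrom) {
  len <- unclass(genome)[chrom]
  if (any(is.na(len))) stop("unknown chromosome: ",
                            paste(chrom[is.na(len)], collapse = ", "))
  unname(len)
}

#' Construct a genomic interval table
#'
#' Intervals are plain data.frames with 0-based half-open coordinates
#' (BED convention): columns `chrom`, `start`, `end` and optional `name`,
#' `score`. All interval-consuming functions in the package accept this
#' layout.
#'
#' @param chrom character vector.
#' @param start,end numeric vectors; 0-based start (inclusive), end
#'   (exclusive), `start < end`.
#' @param name,score optional per-interval annotation.
#' @param genome optional `genome_spec`; if given, bounds are checked.
#' @return data.frame of class `c("interval_df","data.frame")`.
#' @export
intervals <- function(chrom, start, end, name = NA_character_,
                      score = NA_real_, genome = NULL) {
  n <- length(chrom)
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   name = rep_len(as.character(name), n),
                   score = rep_len(as.numeric(score), n),
                   stringsAsFactors = FALSE)
  validate_intervals(df, genome)
  class(df) <- c("interval_df", "data.frame")
  df
}

validate_intervals <- function(df, genome = NULL) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$start != floor(df$start)) || any(df$end != floor(df$end)))
    stop("interval coordinates must be integral")
  if (any(df$start < 0)) stop("interval start < 0")
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop("interval start >= end at row ", bad[1])
  if (!is.null(genome)) {
    over <- df$end > chrom_length(genome, df$chrom)
    if (any(over))
      stop("interval beyond chromosome end at row ", which(over)[1])
  }
  invisible(df)
}

empty_intervals <- function() {
  intervals(character(0), numeric(0), numeric(0))
}

# internal bridge to GenomicRanges (1-based closed)
as_granges <- function(df) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
  if (!is.null(df$score)) S4Vectors::mcols(gr)$score <- df$score
  if (!is.null(df$name)) S4Vectors::mcols(gr)$name <- df$name
  gr
}

granges_to_intervals <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = as.numeric(GenomicRanges::end(gr)),
                   stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(gr)
  df$name <- if ("name" %in% colnames(mc)) as.character(mc$name) else NA_character_
  df$score <- if ("score" %in% colnames(mc)) as.numeric(mc$score) else NA_real_
  class(df) <- c("interval_df", "data.frame")
  df
}
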