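#' Genomic intervals (0-based, half-open)
#'
#' All coordinates in fpkit follow the BED convention: 0-based inclusive
#' `start`, 0-based exclusive `end`. Intervals are plain data frames with
#' columns `contig` (character), `start` (integer) and `end` (integer),
#' so they compose naturally with base R and can be converted losslessly
#' to/from `GenomicRanges::GRanges` (which is 1-based, closed).
#'
#' @param contig character vector of contig names.
#' @param start integer vector of 0-based inclusive start positions.
#' @param end integer vector of 0-based exclusive end positions.
#' @return A data frame with columns `contig`, `start`, `end`.
#' @examples
#' genomic_interval("chr1", 5, 15)
#' @export
genomic_interval <- function(contig, start, end) {
  stopifnot(length(contig) == length(start), length(start) == length(end))
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("interval coordinates must be non-missing integers")
  if (any(start < 0L))
    stop("interval start must be >= 0 (0-based coordinates)")
  bad <- which(end <= start)
  if (length(bad))
    stop(sprintf("interval end must exceed start (first offender: %s:%d-%d)",
                 contig[bad[1]], start[bad[1]], end[bad[1]]))
  data.frame(contig = as.character(contig), start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Interval widths in bp
#' @param x interval data frame (see [genomic_interval()]).
#' @return integer vector of widths.
#' @export
interval_width <- function(x) x$end - x$start

#' Convert fpkit intervals to GRanges
#' @param x interval data frame.
#' @return a `GRanges` (1-based closed coordinates).
#' @export
as_granges <- function(x) {
  GenomicRanges::GRanges(x$contig,
                         IRanges::IRanges(start = x$start + 1L, end = x$end))
}

#' Convert GRanges to fpkit intervals
#' @param gr a `GRanges`.
#' @return interval data frame (0-based half-open).
#' @export
from_granges <- function(gr) {
  genomic_interval(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr) - 1L,
                   GenomicRanges::end(gr))
}

# Validate that intervals fall within contig bounds of a genome.
.check_in_genome <- function(x, genome) {
  len <- stats::setNames(Biostrings::width(genome), names(genome))
  missing <- setdiff(unique(x$contig), names(len))
  if (length(missing))
    stop("contig(s) absent from genome: ", paste(missing, collapse = ", "))
  bad <- which(x$end > len[x$contig])
  if (length(bad))
    stop(sprintf("interval %s:%d-%d extends past contig end (%d)",
                 x$contig[bad[1]], x$start[bad[1]], x$end[bad[1]],
                 len[x$contig[bad[1]]]))
  invisible(TRUE)
}
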