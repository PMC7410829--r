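#' Read a genome from FASTA
#'
#' Loads all records of a FASTA file into a `DNAStringSet`, uppercases the
#' sequence and validates that only A/C/G/T/N occur. Record order is
#' preserved; `N` is kept as-is (positions whose hexamer context contains
#' an N are excluded from bias tallies downstream).
#'
#' @param path path to a FASTA file.
#' @return a named `DNAStringSet` (one entry per contig).
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  # first whitespace-delimited token is the contig name, as samtools does
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate contig names in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (any(Biostrings::width(seqs) == 0L))
    stop("zero-length contig in FASTA")
  chars <- as.character(seqs)
  up <- toupper(chars)
  for (i in seq_along(up)) {
    m <- regexpr("[^ACGTN]", up[[i]])
    if (m > 0L)
      stop(sprintf("illegal character '%s' in contig %s at position %d",
                   substr(up[[i]], m, m), names(seqs)[i], as.integer(m)))
  }
  out <- Biostrings::DNAStringSet(up)
  names(out) <- names(seqs)
  out
}

#' Per-nucleotide cleavage profile for one sample
#'
#' Container for strand-resolved observed DNase I cleavage counts over a
#' genomic interval. `total_tags` is the library-wide number of uniquely
#' mapped cleavage events (used for depth normalisation); it defaults to
#' the sum of counts in the interval when not supplied.
#'
#' @param interval a single-row interval data frame.
#' @param counts_plus,counts_minus non-negative integer vectors, one entry
#'   per interval position.
#' @param total_tags library-wide cleavage count (>= sum of counts).
#' @return an object of class `cleavage_profile`.
#' @export
cleavage_profile <- function(interval, counts_plus, counts_minus,
                             total_tags = NULL) {
  w <- interval_width(interval)
  stopifnot(nrow(interval) == 1L, length(counts_plus) == w,
            length(counts_minus) == w)
  if (any(counts_plus < 0) || any(counts_minus < 0))
    stop("cleavage counts must be non-negative")
  s <- sum(counts_plus) + sum(counts_minus)
  if (is.null(total_tags)) total_tags <- s
  if (total_tags < s) stop("total_tags smaller than counts in interval")
  structure(list(interval = interval,
                 counts_plus = as.numeric(counts_plus),
                 counts_minus = as.numeric(counts_minus),
                 total_tags = as.numeric(total_tags)),
            class = "cleavage_profile")
}

#' @export
print.cleavage_profile <- function(x, ...) {
  cat(sprintf("<cleavage_profile> %s:%d-%d  %d bp, %g cleavages (+%g/-%g), %g library tags\n",
              x$interval$contig, x$interval$start, x$interval$end,
              interval_width(x$interval),
              sum(x$counts_plus) + sum(x$counts_minus),
              sum(x$counts_plus), sum(x$counts_minus), x$total_tags))
  invisible(x)
}

#' Extract per-base cleavage counts from aligned reads
#'
#' Each retained read contributes one cleavage event at the 0-based
#' position of its 5'-most aligned base: the leftmost aligned base for
#' plus-strand reads and the rightmost aligned base for minus-strand reads
#' (optionally shifted by `minus_offset`). Reads flagged as duplicate,
#' unmapped, secondary or QC-fail are excluded, as are reads below
#' `min_mapq`. Events falling outside `interval` are discarded.
#'
#' @param bam path to a coordinate-sorted, indexed BAM file.
#' @param interval single-row interval data frame.
#' @param total_tags library-wide retained read count; when `NULL` it is
#'   computed from the whole BAM with the same flag filters.
#' @param minus_offset integer added to the minus-strand cleavage position
#'   (default 0; hook for enzyme-specific end shifts).
#' @param min_mapq minimum mapping quality (default 0, i.e. no filter).
#' @return a [cleavage_profile()].
#' @export
extract_cleavages <- function(bam, interval, total_tags = NULL,
                              minus_offset = 0L, min_mapq = 0L) {
  stopifnot(nrow(interval) == 1L)
  bf <- Rsamtools::BamFile(bam)
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam)))
    stop("BAM index not found for ", bam)
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isDuplicate = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isNotPassingQualityControls = FALSE)
  # pad the query window so reads whose 5' end falls inside the interval
  # but whose alignment starts outside are still seen
  gr <- GenomicRanges::GRanges(interval$contig,
          IRanges::IRanges(max(1L, interval$start - 1000L),
                           interval$end + 1000L))
  param <- Rsamtools::ScanBamParam(flag = flags, which = gr,
            what = c("pos", "strand", "cigar", "mapq"))
  res <- Rsamtools::scanBam(bf, param = param)[[1]]
  keep <- is.na(res$mapq) | res$mapq >= min_mapq
  if (min_mapq > 0L) keep <- !is.na(res$mapq) & res$mapq >= min_mapq
  pos <- res$pos[keep]; strand <- res$strand[keep]; cigar <- res$cigar[keep]
  refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  # 0-based 5'-most aligned base per strand
  cut0 <- ifelse(strand == "-",
                 (pos + refw - 1L) - 1L + minus_offset,
                 pos - 1L)
  w <- interval_width(interval)
  inw <- cut0 >= interval$start & cut0 < interval$end
  idx <- cut0[inw] - interval$start + 1L
  cp <- tabulate(idx[strand[inw] != "-"], nbins = w)
  cm <- tabulate(idx[strand[inw] == "-"], nbins = w)
  if (is.null(total_tags)) {
    cnt <- Rsamtools::countBam(bf,
             param = Rsamtools::ScanBamParam(flag = flags))
    total_tags <- cnt$records
  }
  cleavage_profile(interval, cp, cm, total_tags = max(total_tags, sum(cp) + sum(cm)))
}

#' Write a per-base value track as bedGraph
#'
#' Runs of equal values are collapsed into single lines; zero runs are
#' omitted. Real values are written with `digits` significant decimal
#' digits (round-trip is exact for integer tracks and exact to `digits`
#' decimals otherwise).
#'
#' @param values numeric vector, one entry per position of `interval`.
#' @param interval single-row interval data frame.
#' @param path output file.
#' @param digits decimal digits used for non-integer values (default 6).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(values, interval, path, digits = 6L) {
  stopifnot(nrow(interval) == 1L, length(values) == interval_width(interval))
  if (any(!is.finite(values))) stop("track values must be finite")
  v <- round(values, digits)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  df <- data.frame(contig = interval$contig,
                   start = interval$start + starts[keep],
                   end = interval$start + ends[keep],
                   value = r$values[keep])
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(df))
    writeLines(sprintf("%s\t%d\t%d\t%.15g", df$contig, df$start, df$end,
                       df$value), con)
  invisible(path)
}

#' Read a bedGraph into a per-base value track
#'
#' @param path bedGraph file.
#' @param interval single-row interval data frame giving the window to
#'   materialise; positions not covered by any bedGraph line are 0.
#' @return numeric vector of length `interval_width(interval)`.
#' @export
read_bedgraph <- function(path, interval) {
  stopifnot(nrow(interval) == 1L)
  gr <- rtracklayer::import(path, format = "bedGraph")
  bg <- from_granges(gr)
  bg$value <- S4Vectors::mcols(gr)$score
  if (any(bg$end <= bg$start)) stop("bedGraph interval with end <= start")
  out <- numeric(interval_width(interval))
  sel <- bg$contig == interval$contig & bg$start < interval$end &
    bg$end > interval$start
  bg <- bg[sel, , drop = FALSE]
  for (i in seq_len(nrow(bg))) {
    lo <- max(bg$start[i], interval$start) - interval$start + 1L
    hi <- min(bg$end[i], interval$end) - interval$start
    out[lo:hi] <- bg$value[i]
  }
  out
}

#' Read a BED file of intervals
#'
#' @param path BED3+ file.
#' @return interval data frame; columns beyond the first three (name,
#'   score, strand, ...) are carried along when present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- from_granges(gr)
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) out <- cbind(out, mc)
  out
}

#' Write intervals as BED
#'
#' Emits BED3 plus any extra columns present (BED6+ layout when `name`,
#' `score`, `strand` are among them).
#'
#' @param x interval data frame, optionally with extra columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  extra <- setdiff(names(x), c("contig", "start", "end"))
  ord <- intersect(c("name", "score", "strand"), extra)
  extra <- c(ord, setdiff(extra, ord))
  df <- x[, c("contig", "start", "end", extra), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read heterozygous-capable variant records from a VCF
#'
#' Parses a VCF 4.x file (GT FORMAT field required) into a data frame of
#' biallelic SNVs with one genotype column per sample, coded as
#' `"hom-ref"`, `"het"`, `"hom-alt"` or `"missing"`.
#'
#' @param path VCF file (plain text or gzip).
#' @return data frame with columns `contig`, `pos` (0-based), `ref`,
#'   `alt`, then one column per sample.
#' @export
read_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep("missing", length(g))
    out[g %in% c("0/0")] <- "hom-ref"
    out[g %in% c("0/1", "1/0")] <- "het"
    out[g %in% c("1/1")] <- "hom-alt"
    out
  }
  gt2 <- apply(gt, 2, code)
  if (is.null(dim(gt2))) gt2 <- matrix(gt2, nrow = nrow(gt),
                                       dimnames = dimnames(gt))
  out <- data.frame(contig = fix$CHROM,
                    pos = as.integer(fix$POS) - 1L,
                    ref = fix$REF, alt = fix$ALT,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(gt2, stringsAsFactors = FALSE))
  out[keep, , drop = FALSE]
}

# run a block with a private RNG state seeded from `seed`; the caller's
# .Random.seed is untouched
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}
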