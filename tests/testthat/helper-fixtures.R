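# shared fixtures built in code at test time

# a dispersion model with exact mean/size trends, for tests that need a
# known null rather than a fitted one
manual_model <- function(r = 8, mu_slope = 1, mu_intercept = 0,
                         fit_range = c(0.5, 500)) {
  structure(list(mu_coef = c(mu_intercept, mu_slope),
                 r_coef = c(log(r), 0),
                 fit_range = fit_range,
                 bin_table = data.frame()),
            class = "dispersion_model")
}

random_genome <- function(len, seed = 42, name = "c1") {
  set.seed(seed)
  g <- Biostrings::DNAStringSet(
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""))
  names(g) <- name
  g
}

# write a tiny SAM and convert to indexed BAM; reads is a data frame with
# columns pos (0-based leftmost), len, strand ("+"/"-"), flag_extra
# (added to the strand flag), and optionally seq
write_test_bam <- function(reads, contig = "c1", contig_len = 10000,
                           dir = withr::local_tempdir(.local_envir = parent.frame())) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sam <- file.path(dir, "t.sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", contig, contig_len))
  if (is.null(reads$seq))
    reads$seq <- vapply(reads$len, function(l)
      paste(rep("A", l), collapse = ""), "")
  if (is.null(reads$flag_extra)) reads$flag_extra <- 0L
  flag <- ifelse(reads$strand == "-", 16L, 0L) + reads$flag_extra
  body <- sprintf("r%d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                  seq_len(nrow(reads)), flag, contig, reads$pos + 1L,
                  reads$len, reads$seq)
  writeLines(c(hdr, body[order(reads$pos)]), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "t"), overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

# bp-level Jaccard between two interval sets on one contig
jaccard_bp <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(0)
  ga <- GenomicRanges::reduce(as_granges(a))
  gb <- GenomicRanges::reduce(as_granges(b))
  inter <- sum(IRanges::width(GenomicRanges::intersect(ga, gb)))
  uni <- sum(IRanges::width(GenomicRanges::union(ga, gb)))
  inter / uni
}
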