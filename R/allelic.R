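#' Tally allele-resolved cleavage reads at heterozygous SNVs
#'
#' For each variant, pools base calls at the variant position across the
#' BAM files of all samples genotyped heterozygous there. Reads flagged
#' duplicate/secondary/QC-fail/unmapped are excluded and bases below
#' `min_baseq` ignored. Bases matching the ref or alt allele increment
#' `n_ref` / `n_alt`; any other base increments `n_other`. Variants with
#' `n_ref + n_alt < min_depth` are flagged untestable (the depth rule is
#' applied to informative reads only).
#'
#' @param bams named character vector of BAM paths (names = sample ids).
#' @param variants variant data frame from [read_variants()] (columns
#'   `contig`, `pos`, `ref`, `alt`, plus one genotype column per sample).
#' @param min_baseq minimum base quality (default 20).
#' @param min_depth minimum informative depth for testability
#'   (default 35).
#' @return data frame: variant columns plus `n_ref`, `n_alt`, `n_other`,
#'   `n_het_samples`, `testable`.
#' @export
tally_alleles <- function(bams, variants, min_baseq = 20L,
                          min_depth = 35L) {
  stopifnot(!is.null(names(bams)))
  nV <- nrow(variants)
  n_ref <- n_alt <- n_other <- n_het <- integer(nV)
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isDuplicate = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isNotPassingQualityControls = FALSE)
  pparam <- Rsamtools::PileupParam(max_depth = 1e6,
                                   min_base_quality = as.integer(min_baseq),
                                   min_mapq = 0L, min_nucleotide_depth = 1L,
                                   distinguish_strands = FALSE,
                                   distinguish_nucleotides = TRUE,
                                   include_deletions = FALSE,
                                   include_insertions = FALSE)
  for (s in names(bams)) {
    if (!s %in% names(variants)) stop("no genotype column for sample ", s)
    het <- which(variants[[s]] == "het")
    if (!length(het)) next
    bf <- Rsamtools::BamFile(bams[[s]])
    hdr <- Rsamtools::scanBamHeader(bf)$targets
    miss <- setdiff(unique(variants$contig[het]), names(hdr))
    if (length(miss))
      stop("variant contig(s) absent from alignments: ",
           paste(miss, collapse = ", "))
    gr <- GenomicRanges::GRanges(variants$contig[het],
            IRanges::IRanges(variants$pos[het] + 1L,
                             variants$pos[het] + 1L))
    sparam <- Rsamtools::ScanBamParam(flag = flags, which = gr)
    pu <- Rsamtools::pileup(bf, scanBamParam = sparam,
                            pileupParam = pparam)
    if (!nrow(pu)) next
    key <- paste(pu$seqnames, pu$pos - 1L)
    for (ii in het) {
      k <- paste(variants$contig[ii], variants$pos[ii])
      rows <- pu[key == k, , drop = FALSE]
      if (!nrow(rows)) next
      nr <- sum(rows$count[rows$nucleotide == variants$ref[ii]])
      na <- sum(rows$count[rows$nucleotide == variants$alt[ii]])
      n_ref[ii] <- n_ref[ii] + nr
      n_alt[ii] <- n_alt[ii] + na
      n_other[ii] <- n_other[ii] + sum(rows$count) - nr - na
      n_het[ii] <- n_het[ii] + 1L
    }
  }
  out <- variants[, c("contig", "pos", "ref", "alt"), drop = FALSE]
  out$n_ref <- n_ref; out$n_alt <- n_alt; out$n_other <- n_other
  out$n_het_samples <- n_het
  out$testable <- (n_ref + n_alt) >= min_depth
  rownames(out) <- NULL
  out
}

#' Two-sided exact binomial allelic-imbalance test
#'
#' For each testable variant, p is the two-sided exact binomial p-value
#' of `n_ref` successes out of `n_ref + n_alt` against `expected_ratio`,
#' computed by doubling the smaller tail and capping at 1 (conservative
#' on discrete counts). BH q-values are computed across the testable
#' variants; a variant is flagged imbalanced when `q <= q_cutoff`.
#'
#' @param counts data frame from [tally_alleles()] (needs `n_ref`,
#'   `n_alt`, `testable`).
#' @param expected_ratio null reference-allele fraction (default 0.5;
#'   expose a measured reference-mapping bias here if available).
#' @param q_cutoff imbalance flag threshold (default 0.2).
#' @return input plus `ratio`, `fold_imbalance`, `p`, `q`, `imbalanced`.
#' @export
imbalance_test <- function(counts, expected_ratio = 0.5, q_cutoff = 0.2) {
  stopifnot(expected_ratio > 0, expected_ratio < 1)
  if (!any(counts$testable)) stop("no testable variants")
  n <- counts$n_ref + counts$n_alt
  ratio <- ifelse(n > 0, counts$n_ref / n, NA_real_)
  lower <- stats::pbinom(counts$n_ref, n, expected_ratio)
  upper <- stats::pbinom(counts$n_ref - 1L, n, expected_ratio,
                         lower.tail = FALSE)
  p <- pmin(1, 2 * pmin(lower, upper))
  p[!counts$testable] <- NA_real_
  q <- rep(NA_real_, nrow(counts))
  q[counts$testable] <- stats::p.adjust(p[counts$testable], method = "BH")
  counts$ratio <- ratio
  counts$fold_imbalance <- ifelse(
    !is.na(ratio) & ratio > 0 & ratio < 1,
    pmax(ratio, 1 - ratio) / pmin(ratio, 1 - ratio), Inf)
  counts$fold_imbalance[is.na(ratio)] <- NA_real_
  counts$p <- p
  counts$q <- q
  counts$imbalanced <- !is.na(q) & q <= q_cutoff
  counts
}

#' Enrichment of imbalanced variants inside footprints
#'
#' Partitions tested variants within DHSs into footprinted versus
#' non-footprinted positions and compares the imbalanced fraction in the
#' two compartments (ratio footprinted/non-footprinted; Fisher's exact
#' test on the 2x2 table). An empty partition, or a zero non-footprinted
#' fraction, yields an `NA`/`Inf` ratio sentinel without error.
#'
#' @param results data frame from [imbalance_test()].
#' @param footprints interval data frame of (consensus) footprints.
#' @param dhs interval data frame of DHSs (variants outside all DHSs are
#'   dropped with a warning).
#' @return list: `summary` data frame (compartment, n tested,
#'   n imbalanced, fraction), `ratio`, `p`, and the annotated `results`
#'   (with `in_footprint`).
#' @export
footprint_overlap_enrichment <- function(results, footprints, dhs) {
  res <- results[results$testable, , drop = FALSE]
  pos_in <- function(iv, contig, pos) {
    out <- logical(length(pos))
    for (i in seq_len(nrow(iv)))
      out <- out | (contig == iv$contig[i] & pos >= iv$start[i] &
                      pos < iv$end[i])
    out
  }
  in_dhs <- pos_in(dhs, res$contig, res$pos)
  if (!all(in_dhs)) {
    warning(sum(!in_dhs), " tested variant(s) outside DHSs dropped")
    res <- res[in_dhs, , drop = FALSE]
  }
  res$in_footprint <- pos_in(footprints, res$contig, res$pos)
  tab <- table(factor(res$in_footprint, c(TRUE, FALSE)),
               factor(res$imbalanced, c(TRUE, FALSE)))
  n_in <- sum(res$in_footprint); n_out <- sum(!res$in_footprint)
  f_in <- if (n_in > 0) sum(res$imbalanced & res$in_footprint) / n_in else NA_real_
  f_out <- if (n_out > 0) sum(res$imbalanced & !res$in_footprint) / n_out else NA_real_
  ratio <- if (is.na(f_in) || is.na(f_out) || (f_in == 0 && f_out == 0))
    NA_real_ else f_in / f_out
  p <- if (n_in > 0 && n_out > 0) stats::fisher.test(tab)$p.value else NA_real_
  list(summary = data.frame(
         compartment = c("footprinted", "non-footprinted"),
         n_tested = c(n_in, n_out),
         n_imbalanced = c(sum(res$imbalanced & res$in_footprint),
                          sum(res$imbalanced & !res$in_footprint)),
         fraction_imbalanced = c(f_in, f_out)),
       ratio = ratio, p = p, results = res)
}
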