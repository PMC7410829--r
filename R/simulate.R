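#' Synthetic cohort specification
#'
#' Describes the generative conditions of a simulated DNase I footprinting
#' cohort: a uniform-ACGT genome carrying non-overlapping DHSs of elevated
#' cleavage rate, a hexamer cleavage-preference table, planted protected
#' footprints with configurable depletion and width, negative-binomial
#' count noise, group-specific footprints, and heterozygous variants that
#' modulate protection on one allele.
#'
#' Defaults describe the benchmark conditions used throughout the test
#' suite: a 2 Mb genome with 500 DHSs of 200 bp, footprints of width
#' 8-30 bp and depletion 0.1-0.4 planted in half the DHSs, log-normal
#' (sdlog 0.25) hexamer bias, NB size r = 8, and 20-40 expected
#' cleavages/bp inside DHSs.
#'
#' @param n_samples named integer vector `c(A = ..., B = ...)`.
#' @param genome_length genome length in bp.
#' @param n_dhs number of DHSs (placed with >= `dhs_gap` bp gaps).
#' @param dhs_width DHS width in bp.
#' @param dhs_gap minimum gap between DHSs (default 500).
#' @param dhs_multiplier range of per-DHS rate multipliers.
#' @param frac_footprinted_dhs fraction of DHSs with planted footprints.
#' @param footprints_per_dhs planted footprints per footprinted DHS.
#' @param footprint_width integer bounds on footprint width (bp).
#' @param footprint_margin minimum footprint distance from DHS edge (bp).
#' @param footprint_spacing minimum spacing between footprints (bp).
#' @param depletion bounds on the depletion ratio delta in (0, 1).
#' @param depth bounds on per-sample expected cleavages/bp in DHSs.
#' @param frac_group_specific fraction of footprints active in only one
#'   group.
#' @param frac_variant_footprints fraction of footprints carrying a
#'   heterozygous variant.
#' @param alt_allele_multiplier multiplicative modifier of
#'   footprint-interior cleavage on the alt allele (default 0.5: the alt
#'   allele halves protected-region cleavage relative to ref).
#' @param bias_sdlog sdlog of the log-normal hexamer preference draw.
#' @param nb_r NB size parameter of the count noise (scalar, applied at
#'   every mean).
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = c(A = 1L, B = 0L),
                        genome_length = 2e6, n_dhs = 500L,
                        dhs_width = 200L, dhs_gap = 500L,
                        dhs_multiplier = c(1, 2),
                        frac_footprinted_dhs = 0.5,
                        footprints_per_dhs = 1L,
                        footprint_width = c(8L, 30L),
                        footprint_margin = 10L, footprint_spacing = 8L,
                        depletion = c(0.1, 0.4), depth = c(20, 40),
                        frac_group_specific = 0,
                        frac_variant_footprints = 0,
                        alt_allele_multiplier = 0.5,
                        bias_sdlog = 0.25, nb_r = 8) {
  stopifnot(all(n_samples >= 0L), sum(n_samples) >= 1L,
            genome_length > 0, n_dhs >= 0L,
            footprint_width[1] <= footprint_width[2],
            depletion[1] <= depletion[2], all(depletion > 0),
            all(depletion < 1), depth[1] <= depth[2], all(depth > 0),
            nb_r > 0)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Random hexamer bias model
#'
#' Draws k-mer preferences i.i.d. log-normal(0, sdlog), rescaled to mean
#' 1 — a synthetic stand-in for the empirically determined DNase I
#' sequence preference table.
#'
#' @param k context width. @param offset cleaved-base index.
#' @param sdlog log-normal spread (default 0.25).
#' @param seed optional private seed.
#' @return a `bias_model`.
#' @export
random_bias_model <- function(k = 6L, offset = 3L, sdlog = 0.25,
                              seed = NULL) {
  draw <- function() stats::rlnorm(4L^k, 0, sdlog)
  pref <- if (is.null(seed)) draw() else .with_seed(seed, draw())
  pref <- pref / mean(pref)
  names(pref) <- .all_kmers(k)
  structure(list(k = as.integer(k), offset = as.integer(offset),
                 pref = pref, total_cleavages = NA_real_,
                 total_contexts = NA_real_),
            class = "bias_model")
}

# place n intervals of widths w within [lo, hi) with >= gap between and
# flush constraints; random but deterministic under the current RNG
.place_intervals <- function(lo, hi, widths, gap) {
  n <- length(widths)
  need <- sum(widths) + max(0L, n - 1L) * gap
  slack <- (hi - lo) - need
  if (slack < 0)
    stop(sprintf("packing infeasible: need %d bp, have %d", need, hi - lo))
  extra <- sort(floor(stats::runif(n, 0, slack + 1)))
  starts <- lo + extra +
    c(0L, cumsum(widths[-n] + gap))
  data.frame(start = as.integer(starts),
             end = as.integer(starts + widths))
}

#' Simulate cohort ground truth
#'
#' Generates the complete, reproducible description of a synthetic
#' cohort: a uniform-ACGT genome; non-overlapping DHSs with per-DHS rate
#' multipliers; planted footprints (interval, depletion, group
#' specificity) placed inside DHSs with edge margins and minimum spacing;
#' heterozygous variants inside a subset of footprints with per-allele
#' cleavage modifiers; a random hexamer bias table; and per-sample depths
#' and group labels. Everything is deterministic given `seed`.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return a list of class `simulation_truth`.
#' @export
simulate_truth <- function(spec, seed) {
  .with_seed(seed, {
    L <- as.integer(spec$genome_length)
    letters <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    genome <- Biostrings::DNAStringSet(paste(letters, collapse = ""))
    names(genome) <- "chrS"
    dhs <- if (spec$n_dhs > 0L) {
      d <- .place_intervals(0L, L, rep(spec$dhs_width, spec$n_dhs),
                            spec$dhs_gap)
      data.frame(contig = "chrS", d,
                 multiplier = stats::runif(spec$n_dhs,
                                           spec$dhs_multiplier[1],
                                           spec$dhs_multiplier[2]))
    } else data.frame(contig = character(), start = integer(),
                      end = integer(), multiplier = numeric())
    n_fp_dhs <- round(spec$frac_footprinted_dhs * nrow(dhs))
    fp_dhs <- sort(sample(seq_len(nrow(dhs)), n_fp_dhs))
    fps <- list()
    for (i in fp_dhs) {
      k <- spec$footprints_per_dhs
      w <- sample(spec$footprint_width[1]:spec$footprint_width[2], k,
                  replace = TRUE)
      pl <- .place_intervals(dhs$start[i] + spec$footprint_margin,
                             dhs$end[i] - spec$footprint_margin,
                             w, spec$footprint_spacing)
      grp <- ifelse(stats::runif(k) < spec$frac_group_specific,
                    sample(c("A", "B"), k, replace = TRUE), "none")
      fps[[length(fps) + 1L]] <- data.frame(
        contig = "chrS", pl,
        delta = stats::runif(k, spec$depletion[1], spec$depletion[2]),
        group = grp, dhs_idx = i, stringsAsFactors = FALSE)
    }
    footprints <- if (length(fps)) do.call(rbind, fps) else
      data.frame(contig = character(), start = integer(), end = integer(),
                 delta = numeric(), group = character(), dhs_idx = integer())
    rownames(footprints) <- NULL
    # variants: one het SNV inside a subset of footprints; individual 1
    # is heterozygous, individual 2 homozygous reference
    nv <- round(spec$frac_variant_footprints * nrow(footprints))
    var_fp <- if (nv > 0) sort(sample(seq_len(nrow(footprints)), nv)) else integer()
    variants <- data.frame(contig = character(), pos = integer(),
                           ref = character(), alt = character(),
                           footprint_idx = integer(), m_ref = numeric(),
                           m_alt = numeric(), stringsAsFactors = FALSE)
    if (length(var_fp)) {
      pos <- vapply(var_fp, function(j)
        as.integer(sample(footprints$start[j]:(footprints$end[j] - 1L), 1)), 0L)
      ref <- letters[pos + 1L]
      alt <- vapply(ref, function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
      variants <- data.frame(contig = "chrS", pos = pos, ref = ref,
                             alt = unname(alt), footprint_idx = var_fp,
                             m_ref = 1, m_alt = spec$alt_allele_multiplier,
                             stringsAsFactors = FALSE)
    }
    bias <- random_bias_model(6L, 3L, spec$bias_sdlog)
    ns <- spec$n_samples
    groups <- rep(names(ns), times = ns)
    samples <- data.frame(
      sample = sprintf("s%s%02d", groups,
                       unlist(lapply(ns, seq_len))[seq_along(groups)]),
      group = groups,
      depth = stats::runif(length(groups), spec$depth[1], spec$depth[2]),
      individual = rep_len(c("ind1", "ind2"), length(groups)),
      stringsAsFactors = FALSE)
    structure(list(spec = spec, seed = seed, genome = genome, dhs = dhs,
                   footprints = footprints, variants = variants,
                   bias = bias, nb_r = spec$nb_r, samples = samples),
              class = "simulation_truth")
  })
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("<simulation_truth> seed=%d: %g bp genome, %d DHSs, %d footprints, %d variants, %d samples\n",
              x$seed, sum(Biostrings::width(x$genome)), nrow(x$dhs),
              nrow(x$footprints), nrow(x$variants), nrow(x$samples)))
  invisible(x)
}

#' Simulate one sample's cleavage profiles
#'
#' Per DHS position i, the cleavage rate is
#' `lambda_i = depth * dhs_multiplier * bias(context_i)` times the
#' footprint depletion `delta` where the position lies inside a footprint
#' active for this sample's group; the rate is split equally between
#' strands with strand-specific (reverse-complement) bias lookup, and
#' counts are drawn NB(lambda, r) independently per position and strand.
#' Outside DHSs the rate is zero. At variant positions inside
#' variant-linked footprints the two alleles of a heterozygous sample
#' each contribute half the rate, modified per allele; the simulated
#' allele-of-origin counts are recorded.
#'
#' @param truth a [simulate_truth()] result.
#' @param sample_id a sample id from `truth$samples`.
#' @param seed integer seed (private stream).
#' @return list with `profiles` (list of [cleavage_profile()], one per
#'   DHS), `allele_counts` (data frame: variant, ref/alt-origin counts at
#'   the variant position) and `total_tags`.
#' @export
simulate_sample <- function(truth, sample_id, seed) {
  srow <- truth$samples[truth$samples$sample == sample_id, ]
  if (!nrow(srow)) stop("unknown sample: ", sample_id)
  spec <- truth$spec
  r <- truth$nb_r
  .with_seed(seed, {
    profiles <- vector("list", nrow(truth$dhs))
    ac <- list()
    for (i in seq_len(nrow(truth$dhs))) {
      iv <- genomic_interval(truth$dhs$contig[i], truth$dhs$start[i],
                             truth$dhs$end[i])
      w <- interval_width(iv)
      base <- srow$depth * truth$dhs$multiplier[i]
      prot <- rep(1, w)
      fsel <- which(truth$footprints$dhs_idx == i)
      for (j in fsel) {
        g <- truth$footprints$group[j]
        if (g != "none" && g != srow$group) next
        lo <- truth$footprints$start[j] - iv$start + 1L
        hi <- truth$footprints$end[j] - iv$start
        prot[lo:hi] <- truth$footprints$delta[j]
      }
      # allele-specific modulation at variant-linked footprints
      amod <- rep(1, w)       # multiplies the protected rate
      vsel <- which(truth$variants$footprint_idx %in% fsel)
      for (v in vsel) {
        j <- truth$variants$footprint_idx[v]
        g <- truth$footprints$group[j]
        if (g != "none" && g != srow$group) next
        gt <- if (srow$individual == "ind1") "het" else "hom-ref"
        lo <- truth$footprints$start[j] - iv$start + 1L
        hi <- truth$footprints$end[j] - iv$start
        m <- switch(gt,
                    "het" = (truth$variants$m_ref[v] + truth$variants$m_alt[v]) / 2,
                    "hom-ref" = truth$variants$m_ref[v],
                    "hom-alt" = truth$variants$m_alt[v])
        amod[lo:hi] <- m
      }
      cp <- cm <- numeric(w)
      # each strand draws NB(lambda/2, r/2); the strands share the
      # success probability, so the combined per-position count is
      # exactly NB(lambda, r)
      for (st in c("+", "-")) {
        b <- .bias_values(truth$genome, iv, truth$bias, st)
        lam <- base * prot * amod * b / 2
        y <- stats::rnbinom(w, size = r / 2, mu = lam)
        if (st == "+") cp <- y else cm <- y
      }
      # allele-of-origin draws at variant positions of het samples
      for (v in vsel) {
        j <- truth$variants$footprint_idx[v]
        g <- truth$footprints$group[j]
        if (g != "none" && g != srow$group) next
        if (srow$individual != "ind1") next
        p0 <- truth$variants$pos[v] - iv$start + 1L
        bp <- .bias_values(truth$genome, iv, truth$bias, "+")[p0]
        bm <- .bias_values(truth$genome, iv, truth$bias, "-")[p0]
        # the total cleavage count at the site carries the NB technical
        # variability; each cleavage's allele of origin is then a
        # Bernoulli draw proportional to the per-allele rates
        lam_allele <- base * prot[p0] * (bp + bm) / 2 / 2  # per allele
        mref <- lam_allele * truth$variants$m_ref[v]
        malt <- lam_allele * truth$variants$m_alt[v]
        tot <- stats::rnbinom(1, size = r, mu = mref + malt)
        cref <- stats::rbinom(1, tot, mref / (mref + malt))
        calt <- tot - cref
        cp[p0] <- tot %/% 2 + tot %% 2
        cm[p0] <- tot %/% 2
        ac[[length(ac) + 1L]] <- data.frame(
          contig = truth$variants$contig[v], pos = truth$variants$pos[v],
          ref = truth$variants$ref[v], alt = truth$variants$alt[v],
          n_ref = cref, n_alt = calt, sample = sample_id,
          stringsAsFactors = FALSE)
      }
      profiles[[i]] <- cleavage_profile(iv, cp, cm)
    }
    total <- sum(vapply(profiles, function(p)
      sum(p$counts_plus) + sum(p$counts_minus), 0))
    for (i in seq_along(profiles)) profiles[[i]]$total_tags <- total
    allele_counts <- if (length(ac)) do.call(rbind, ac) else
      data.frame(contig = character(), pos = integer(), ref = character(),
                 alt = character(), n_ref = integer(), n_alt = integer(),
                 sample = character(), stringsAsFactors = FALSE)
    list(profiles = profiles, allele_counts = allele_counts,
         total_tags = total)
  })
}

# single bedGraph covering all of one sample's DHS profiles
.write_cohort_bedgraph <- function(profiles, strand, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in profiles) {
    v <- if (strand == "+") p$counts_plus else p$counts_minus
    r <- rle(v)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%g", p$interval$contig,
                         p$interval$start + starts[keep],
                         p$interval$start + ends[keep],
                         r$values[keep]), con)
  }
  invisible(path)
}

.write_cohort_vcf <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  samp <- truth$samples$sample
  gt <- vapply(truth$samples$individual,
               function(i) if (i == "ind1") "0/1" else "0/0", "")
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", names(truth$genome)[1],
                       Biostrings::width(truth$genome)[1]),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samp), collapse = "\t")),
             con)
  v <- truth$variants
  for (i in seq_len(nrow(v)))
    writeLines(paste(c(v$contig[i], v$pos[i] + 1L, sprintf("var%d", i),
                       v$ref[i], v$alt[i], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  invisible(path)
}

#' Simulate and write a full cohort
#'
#' Composition of [simulate_truth()] and [simulate_sample()] for every
#' sample (per-sample seeds derived from `seed`). When `out_dir` is
#' given, writes the genome FASTA, per-sample per-strand cleavage
#' bedGraphs, a truth BED of planted footprints (name = delta:group), a
#' VCF of planted heterozygous variants, and a YAML manifest listing
#' every file with its md5 checksum.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @param out_dir optional output directory (created if needed).
#' @return list with `truth`, `samples` (named list of
#'   [simulate_sample()] results) and `files` (named paths, when
#'   written).
#' @export
simulate_cohort <- function(spec, seed, out_dir = NULL) {
  truth <- simulate_truth(spec, seed)
  sims <- list()
  for (i in seq_len(nrow(truth$samples))) {
    sid <- truth$samples$sample[i]
    sims[[sid]] <- simulate_sample(truth, sid, seed + 7919L * i)
  }
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(fasta = file.path(out_dir, "genome.fa"),
               truth_bed = file.path(out_dir, "footprints_truth.bed"),
               dhs_bed = file.path(out_dir, "dhs.bed"),
               vcf = file.path(out_dir, "variants.vcf"),
               manifest = file.path(out_dir, "manifest.yaml"))
    Biostrings::writeXStringSet(truth$genome, files["fasta"])
    tb <- truth$footprints
    tb$name <- sprintf("%.3f:%s", tb$delta, tb$group)
    write_bed(tb[, c("contig", "start", "end", "name")], files["truth_bed"])
    write_bed(truth$dhs[, c("contig", "start", "end")], files["dhs_bed"])
    .write_cohort_vcf(truth, files["vcf"])
    for (sid in names(sims)) {
      for (st in c("plus", "minus")) {
        f <- file.path(out_dir, sprintf("%s.%s.bedGraph", sid, st))
        .write_cohort_bedgraph(sims[[sid]]$profiles,
                               if (st == "plus") "+" else "-", f)
        files[paste(sid, st, sep = ".")] <- f
      }
    }
    listed <- files[names(files) != "manifest"]
    manifest <- list(seed = seed,
                     samples = truth$samples$sample,
                     files = lapply(seq_along(listed), function(i)
                       list(path = basename(listed[[i]]),
                            md5 = unname(tools::md5sum(listed[[i]])))))
    yaml::write_yaml(manifest, files["manifest"])
  }
  list(truth = truth, samples = sims, files = files)
}
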