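#' Cross-sample footprint prior
#'
#' Per-nucleotide prior probability of protection from the de novo calls
#' of N samples, with Laplace pseudocounts:
#' `prior[i] = (k[i] + a) / (N + a + b)` where `k[i]` is the number of
#' samples whose calls cover position i. Pseudocounts keep the prior
#' strictly inside (0, 1) so a footprint unseen in the cohort can still
#' be recovered by a deep sample.
#'
#' @param calls_by_sample list (one element per sample) of footprint call
#'   data frames with `contig`, `start`, `end` columns.
#' @param interval single-row interval data frame to evaluate over.
#' @param a,b pseudocounts (default 1 each).
#' @return numeric vector of priors, one per interval position.
#' @export
footprint_prior <- function(calls_by_sample, interval, a = 1, b = 1) {
  N <- length(calls_by_sample)
  stopifnot(N >= 1L)
  w <- interval_width(interval)
  k <- numeric(w)
  for (calls in calls_by_sample) {
    if (is.null(calls) || !nrow(calls)) next
    sel <- calls$contig == interval$contig & calls$start < interval$end &
      calls$end > interval$start
    cov <- numeric(w)
    cc <- calls[sel, , drop = FALSE]
    for (j in seq_len(nrow(cc))) {
      lo <- max(cc$start[j], interval$start) - interval$start + 1L
      hi <- min(cc$end[j], interval$end) - interval$start
      cov[lo:hi] <- 1
    }
    k <- k + cov
  }
  (k + a) / (N + a + b)
}

#' Occupied / unoccupied count likelihoods
#'
#' Unoccupied: NB pmf of the observed count at the fitted mean and size.
#' Occupied: the mean NB pmf over a grid of depletion ratios applied to
#' the mean (default 0.05-0.75 in steps of 0.05), i.e. a uniform mixture
#' over plausible protection strengths.
#'
#' @param obs observed counts (vector).
#' @param exp expected rates (vector).
#' @param model a `dispersion_model`.
#' @param depletion_grid depletion ratios in (0, 1\].
#' @param min_expected positions below this expected rate are flagged
#'   untested (likelihoods returned as NA).
#' @return data frame with columns `L_occ`, `L_unocc`, `tested`.
#' @export
occupancy_likelihoods <- function(obs, exp, model,
                                  depletion_grid = seq(0.05, 0.75, by = 0.05),
                                  min_expected = 0.1) {
  stopifnot(length(obs) == length(exp), all(depletion_grid > 0))
  tested <- is.finite(exp) & exp >= min_expected
  L_occ <- L_un <- rep(NA_real_, length(obs))
  if (any(tested)) {
    mu <- mu_fn(model, exp[tested])
    r <- r_fn(model, exp[tested])
    y <- obs[tested]
    L_un[tested] <- stats::dnbinom(y, size = r, mu = mu)
    acc <- 0
    for (d in depletion_grid)
      acc <- acc + stats::dnbinom(y, size = r, mu = d * mu)
    L_occ[tested] <- acc / length(depletion_grid)
  }
  data.frame(L_occ = L_occ, L_unocc = L_un, tested = tested)
}

#' Per-nucleotide footprint posterior for one sample
#'
#' `posterior = prior * L_occ / (prior * L_occ + (1 - prior) * L_unocc)`.
#' The likelihoods are evaluated over a small centred evidence window
#' (`2 * evidence_half + 1` positions): protection by a bound factor
#' occludes a run of adjacent phosphate bonds, so the occupied model
#' shares one depletion ratio across the window,
#' `L_occ(i) = mean over the grid of prod_j NB(obs_j; delta * mu_j, r_j)`,
#' while the unoccupied model is the product of the per-position null
#' pmfs. With `evidence_half = 0` this reduces exactly to
#' [occupancy_likelihoods()] per position. Untested positions contribute
#' no likelihood factors; positions that are themselves untested inherit
#' the prior and are flagged.
#'
#' @param observed a [cleavage_profile()].
#' @param expected the matching [expected_profile()].
#' @param model a `dispersion_model`.
#' @param prior per-position prior vector (from [footprint_prior()]).
#' @param depletion_grid depletion ratios of the occupied mixture.
#' @param min_expected untested threshold (default 0.1).
#' @param evidence_half half-width of the likelihood evidence window in
#'   bp (default 1, a 3-bp window).
#' @param sample_id sample label.
#' @return object of class `posterior_track`: interval, `posterior`,
#'   `prior`, `tested`, `sample`.
#' @export
posterior_track <- function(observed, expected, model, prior,
                            depletion_grid = seq(0.05, 0.75, by = 0.05),
                            min_expected = 0.1, evidence_half = 1L,
                            sample_id = "sample") {
  obs <- observed$counts_plus + observed$counts_minus
  e <- expected$expected
  n <- length(obs)
  stopifnot(length(prior) == n, length(e) == n)
  tested <- is.finite(e) & e >= min_expected
  mu <- r <- rep(NA_real_, n)
  mu[tested] <- mu_fn(model, e[tested])
  r[tested] <- r_fn(model, e[tested])
  ll_un <- numeric(n)
  ll_un[tested] <- stats::dnbinom(obs[tested], size = r[tested],
                                  mu = mu[tested], log = TRUE)
  # windowed log-likelihoods; untested positions contribute 0 (no factor)
  L_un <- exp(.winsum(ll_un, evidence_half))
  L_occ <- 0
  for (d in depletion_grid) {
    ll_d <- numeric(n)
    ll_d[tested] <- stats::dnbinom(obs[tested], size = r[tested],
                                   mu = d * mu[tested], log = TRUE)
    L_occ <- L_occ + exp(.winsum(ll_d, evidence_half))
  }
  L_occ <- L_occ / length(depletion_grid)
  post <- prior
  num <- prior[tested] * L_occ[tested]
  den <- num + (1 - prior[tested]) * L_un[tested]
  post[tested] <- ifelse(den > 0, num / den, prior[tested])
  post[prior == 0] <- 0
  structure(list(interval = observed$interval, posterior = post,
                 prior = prior, tested = tested, sample = sample_id),
            class = "posterior_track")
}

#' Extract high-posterior footprinted segments
#'
#' Maximal runs of positions with posterior strictly above `cutoff`
#' (default 0.99, the consensus-index threshold).
#'
#' @param track a [posterior_track()].
#' @param cutoff posterior cutoff in (0, 1).
#' @return data frame: `contig`, `start`, `end`, `mean_posterior`,
#'   `sample`.
#' @export
sample_segments <- function(track, cutoff = 0.99) {
  stopifnot(cutoff > 0, cutoff < 1)
  pass <- track$posterior > cutoff
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), mean_posterior = numeric(),
                      sample = character(), stringsAsFactors = FALSE)
  if (!any(pass)) return(empty)
  r <- rle(pass)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  mp <- vapply(seq_len(nrow(runs)),
               function(i) mean(track$posterior[runs$start[i]:runs$end[i]]), 0)
  data.frame(contig = track$interval$contig,
             start = track$interval$start + runs$start - 1L,
             end = track$interval$start + runs$end,
             mean_posterior = mp, sample = track$sample,
             stringsAsFactors = FALSE)
}

# lower / upper median of an integer vector
.lower_median <- function(x) sort(x)[floor((length(x) + 1) / 2)]
.upper_median <- function(x) sort(x)[ceiling((length(x) + 1) / 2)]

#' Collate per-sample footprinted segments into a consensus index
#'
#' Greedy centroid collation, applied per contig: repeatedly (1) find the
#' genomic position covered by the largest number of remaining segments
#' (ties: leftmost); (2) gather all segments covering it; (3) emit the
#' consensus interval `[lower-median start, upper-median end)` of the
#' gathered segments with support = number of distinct contributing
#' samples; (4) remove the gathered segments. The result is independent
#' of segment input order. Abutting consensus footprints are not merged.
#'
#' @param segments data frame of per-sample segments: `contig`, `start`,
#'   `end`, `sample` and optionally `mean_posterior`.
#' @return list with `footprints` (data frame: `contig`, `start`, `end`,
#'   `id`, `n_samples`, `mean_posterior`) and `members` (data frame
#'   linking each input segment to its consensus `id`).
#' @export
consensus_index <- function(segments) {
  if (!nrow(segments))
    return(list(footprints = data.frame(contig = character(),
                  start = integer(), end = integer(), id = character(),
                  n_samples = integer(), mean_posterior = numeric()),
                members = data.frame()))
  if (is.null(segments$mean_posterior))
    segments$mean_posterior <- NA_real_
  fps <- list(); mems <- list(); idn <- 0L
  for (ctg in sort(unique(segments$contig))) {
    seg <- segments[segments$contig == ctg, , drop = FALSE]
    # canonical order so ties in coverage resolve by coordinate only
    seg <- seg[order(seg$start, seg$end, seg$sample), , drop = FALSE]
    while (nrow(seg)) {
      ir <- IRanges::IRanges(seg$start + 1L, seg$end)
      cov <- IRanges::coverage(ir)
      rv <- S4Vectors::runValue(cov)
      rl <- S4Vectors::runLength(cov)
      mx <- max(rv)
      first <- which(rv == mx)[1]
      pos1 <- if (first == 1L) 1L else sum(rl[seq_len(first - 1L)]) + 1L
      hit <- seg$start + 1L <= pos1 & seg$end >= pos1
      g <- seg[hit, , drop = FALSE]
      idn <- idn + 1L
      id <- sprintf("fp%05d", idn)
      fps[[idn]] <- data.frame(contig = ctg,
        start = .lower_median(g$start), end = .upper_median(g$end),
        id = id, n_samples = length(unique(g$sample)),
        mean_posterior = mean(g$mean_posterior),
        stringsAsFactors = FALSE)
      mems[[idn]] <- data.frame(id = id, sample = g$sample,
                                contig = ctg, start = g$start, end = g$end,
                                stringsAsFactors = FALSE)
      seg <- seg[!hit, , drop = FALSE]
    }
  }
  fp <- do.call(rbind, fps)
  mm <- do.call(rbind, mems)
  ord <- order(fp$contig, fp$start, fp$end)
  fp <- fp[ord, , drop = FALSE]
  rownames(fp) <- rownames(mm) <- NULL
  list(footprints = fp, members = mm)
}

#' Assign motif hits to consensus footprints
#'
#' A motif hit is assigned to a footprint when the overlap between the
#' two intervals covers at least `min_overlap_frac` of the motif length.
#' Assigned hits are ranked by match score (descending); footprints are
#' classed `"unambiguous"` (one candidate), `"ranked"` (several) or
#' `"unassigned"`.
#'
#' @param footprints consensus footprint data frame (needs `contig`,
#'   `start`, `end`, `id`).
#' @param hits motif hit data frame: `contig`, `start`, `end`, `motif`,
#'   `score`, `strand`.
#' @param min_overlap_frac minimum overlap as a fraction of motif length
#'   (default 0.9).
#' @return list with `assignments` (footprint id, motif, score, rank) and
#'   `footprints` (input plus `n_motifs` and `class` columns).
#' @export
assign_motifs <- function(footprints, hits, min_overlap_frac = 0.9) {
  stopifnot(min_overlap_frac > 0, min_overlap_frac <= 1)
  asn <- data.frame(id = character(), motif = character(),
                    score = numeric(), rank = integer(),
                    stringsAsFactors = FALSE)
  if (nrow(footprints) && nrow(hits)) {
    gf <- as_granges(footprints)
    gh <- as_granges(hits)
    ov <- GenomicRanges::findOverlaps(gf, gh)
    if (length(ov)) {
      qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
      inter <- pmin(footprints$end[qi], hits$end[si]) -
        pmax(footprints$start[qi], hits$start[si])
      frac <- inter / (hits$end[si] - hits$start[si])
      keep <- frac >= min_overlap_frac
      if (any(keep)) {
        asn <- data.frame(id = footprints$id[qi[keep]],
                          motif = hits$motif[si[keep]],
                          score = hits$score[si[keep]],
                          stringsAsFactors = FALSE)
        asn <- asn[order(asn$id, -asn$score), , drop = FALSE]
        asn$rank <- stats::ave(asn$score, asn$id,
                               FUN = function(s) rank(-s, ties.method = "first"))
        rownames(asn) <- NULL
      }
    }
  }
  n <- table(asn$id)
  footprints$n_motifs <- as.integer(n[footprints$id])
  footprints$n_motifs[is.na(footprints$n_motifs)] <- 0L
  footprints$class <- ifelse(footprints$n_motifs == 0L, "unassigned",
                       ifelse(footprints$n_motifs == 1L, "unambiguous",
                              "ranked"))
  list(assignments = asn, footprints = footprints)
}
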