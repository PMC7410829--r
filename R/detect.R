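#' Detection parameters
#'
#' Bundles the tunable parameters of per-sample de novo footprint
#' discovery.
#'
#' @param window_half smoothing half-width (bp) for the expected-rate
#'   model (default 50, a 101-bp window).
#' @param widths odd window widths (bp) for the Stouffer combination
#'   (default 3,5,7,9,11,13); the statistic is the minimum over widths.
#' @param fdr_threshold empirical-FDR calling threshold (default 0.01).
#' @param merge_gap maximum run gap (bp) bridged when segmenting
#'   (default 3).
#' @param min_width minimum footprint width in bp (default 6; genomic
#'   footprints are rarely narrower than ~7 bp).
#' @param n_null number of null replicates for the empirical FDR
#'   (default 1; raise for sharper FDR resolution on small interval sets).
#' @param min_expected minimum expected rate for a position to be tested
#'   (default 0.1).
#' @param z_cap cap applied to per-position z-values from untested or
#'   p = 1 positions (default 8.2).
#' @param refine_slack maximum boundary shift (bp) allowed to the
#'   likelihood-based boundary refinement of each call (default 4;
#'   0 disables refinement). Refinement never changes which elements are
#'   called, only the reported edges.
#' @param seed RNG seed for the null replicates.
#' @return a list of class `detect_params`.
#' @export
detect_params <- function(window_half = 50L, widths = c(3L, 5L, 7L, 9L, 11L, 13L),
                          fdr_threshold = 0.01, merge_gap = 3L,
                          min_width = 6L, n_null = 1L, min_expected = 0.1,
                          z_cap = 8.2, refine_slack = 4L, seed = 1L) {
  if (any(widths %% 2L == 0L)) stop("window widths must be odd")
  structure(list(window_half = window_half, widths = widths,
                 fdr_threshold = fdr_threshold, merge_gap = merge_gap,
                 min_width = min_width, n_null = n_null,
                 min_expected = min_expected, z_cap = z_cap,
                 refine_slack = refine_slack, seed = seed),
            class = "detect_params")
}

#' Likelihood-based refinement of call boundaries
#'
#' The windowed statistic that drives segmentation smears protection
#' signal by up to half a window, so run edges are noisy. For each call,
#' this step scans boundary pairs within `slack` bp of the segmented
#' edges and keeps the pair maximizing a two-level NB likelihood: counts
#' inside the boundaries at `delta * mu` (with `delta` estimated from
#' the call itself) and flanking counts at the null `mu`. Flank
#' positions covered by another call, or untested, contribute no
#' likelihood factor. The call/no-call decision is never revisited.
#'
#' @param calls call data frame (genomic coordinates) within one
#'   analyzed interval.
#' @param obs,exp,tested per-position vectors over the interval.
#' @param interval the analyzed interval (single row).
#' @param model a `dispersion_model`.
#' @param slack maximum boundary shift in bp.
#' @return `calls` with refined `start`, `end`, `width`.
#' @export
refine_boundaries <- function(calls, obs, exp, tested, interval, model,
                              slack = 4L) {
  if (!nrow(calls) || slack <= 0L) return(calls)
  n <- length(obs)
  mu <- mu_fn(model, exp)
  r <- r_fn(model, exp)
  ll_null <- rep(0, n)
  ll_null[tested] <- stats::dnbinom(obs[tested], size = r[tested],
                                    mu = mu[tested], log = TRUE)
  occupied <- rep(FALSE, n)
  rs <- calls$start - interval$start + 1L
  re <- calls$end - interval$start
  for (ci in seq_len(nrow(calls))) occupied[rs[ci]:re[ci]] <- TRUE
  for (ci in seq_len(nrow(calls))) {
    s <- rs[ci]; e <- re[ci]
    lo <- max(1L, s - slack); hi <- min(n, e + slack)
    # usable flank: tested, not inside any other call
    other <- occupied
    other[s:e] <- FALSE
    usable <- tested & !other
    span <- sum(mu[s:e][tested[s:e]])
    if (span <= 0) next
    delta <- min(0.9, max(0.02, sum(obs[s:e][tested[s:e]]) / span))
    ll_in <- rep(0, n)
    ll_in[tested] <- stats::dnbinom(obs[tested], size = r[tested],
                                    mu = delta * mu[tested], log = TRUE)
    best <- c(-Inf, s, e)
    for (a in lo:min(s + slack, e)) {
      for (b in max(e - slack, a + 2L):hi) {
        idx <- a:b
        fl <- setdiff(lo:hi, idx)
        ll <- sum(ll_in[idx][tested[idx] & !other[idx]]) +
          sum(ll_null[fl][usable[fl]])
        if (ll > best[1]) best <- c(ll, a, b)
      }
    }
    rs[ci] <- best[2]; re[ci] <- best[3]
  }
  calls$start <- interval$start + rs - 1L
  calls$end <- interval$start + re
  calls$width <- calls$end - calls$start
  calls
}

# exact rolling sum over full windows; x is padded with `pad` so edge
# windows are completed with the padding value
.rollsum_padded <- function(x, half, pad) {
  n <- length(x)
  xp <- c(rep(pad, half), x, rep(pad, half))
  cs <- c(0, cumsum(xp))
  cs[(2L * half + 1L) + seq_len(n)] - cs[seq_len(n)]
}

#' Windowed Stouffer depletion statistic
#'
#' Converts per-position depletion p-values to z-values
#' (`qnorm(p)`; untested or p = 1 positions contribute the cap `z_cap`),
#' combines them over centred windows of each width w as
#' `Z_w(i) = sum(z over window) / sqrt(w)`, and takes the minimum over
#' widths. More negative = more protected. Windows extending past the
#' array are completed with the (null) cap value.
#'
#' @param p per-position p-values in (0, 1].
#' @param tested logical per-position tested flags.
#' @param widths odd window widths.
#' @param z_cap cap for untested contributions (default 8.2).
#' @return numeric vector of combined statistics.
#' @export
windowed_stat <- function(p, tested = rep(TRUE, length(p)),
                          widths = c(3L, 5L, 7L, 9L, 11L, 13L),
                          z_cap = 8.2) {
  if (any(widths %% 2L == 0L) || any(widths < 1L))
    stop("window widths must be odd and >= 1")
  z <- stats::qnorm(pmax(p, 1e-320))
  z[!tested | p >= 1] <- z_cap
  z <- pmin(z, z_cap)
  stat <- rep(Inf, length(z))
  for (w in widths) {
    half <- (w - 1L) %/% 2L
    zw <- .rollsum_padded(z, half, z_cap) / sqrt(w)
    stat <- pmin(stat, zw)
  }
  stat
}

#' Empirical FDR from resampled null statistics
#'
#' For threshold t (statistics are "significant when small"):
#' `FDR(t) = (#\{null <= t\} / R) / max(1, #\{obs <= t\})`, clipped to
#' \[0, 1\], evaluated at every observed statistic and then monotonized
#' step-up (each position receives the minimum FDR over all thresholds at
#' least as large as its own statistic), which makes FDR non-decreasing
#' in the statistic.
#'
#' @param observed_stats numeric vector of observed combined statistics.
#' @param null_stats list of numeric vectors, one per null replicate,
#'   produced by pushing [sample_null()] draws through the identical
#'   statistic pipeline.
#' @return numeric vector of per-position FDR values.
#' @export
empirical_fdr <- function(observed_stats, null_stats) {
  if (!is.list(null_stats)) null_stats <- list(null_stats)
  R <- length(null_stats)
  if (R == 0L) stop("at least one null replicate is required")
  nul <- sort(unlist(null_stats))
  obs_sorted <- sort(observed_stats)
  n_null_le <- findInterval(observed_stats, nul)
  n_obs_le <- findInterval(observed_stats, obs_sorted)
  raw <- pmin(1, pmax(0, (n_null_le / R) / pmax(1, n_obs_le)))
  ord <- order(observed_stats)
  mono_sorted <- rev(cummin(rev(raw[ord])))
  fdr <- numeric(length(raw))
  fdr[ord] <- mono_sorted
  fdr
}

#' Segment per-position FDR into footprint calls
#'
#' Positions at or below the FDR threshold form runs; runs separated by
#' at most `merge_gap` failing positions are merged; merged runs narrower
#' than `min_width` are discarded.
#'
#' @param fdr per-position FDR values.
#' @param interval single-row interval data frame the track covers.
#' @param threshold FDR cutoff in (0, 1) (default 0.01).
#' @param merge_gap maximum bridged gap in bp (default 3).
#' @param min_width minimum call width in bp (default 6).
#' @param sample_id sample label carried into the calls.
#' @return data frame of footprint calls: `contig`, `start`, `end`,
#'   `width`, `best_fdr`, `sample`.
#' @export
segment_footprints <- function(fdr, interval, threshold = 0.01,
                               merge_gap = 3L, min_width = 6L,
                               sample_id = "sample") {
  stopifnot(threshold > 0, threshold < 1)
  pass <- fdr <= threshold
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), width = integer(),
                      best_fdr = numeric(), sample = character(),
                      stringsAsFactors = FALSE)
  if (!any(pass)) return(empty)
  r <- rle(pass)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs across small gaps
  if (nrow(runs) > 1L) {
    merged <- list()
    cur <- runs[1L, ]
    for (i in 2L:nrow(runs)) {
      gap <- runs$start[i] - cur$end - 1L
      if (gap <= merge_gap) {
        cur$end <- runs$end[i]
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- runs[i, ]
      }
    }
    merged[[length(merged) + 1L]] <- cur
    runs <- do.call(rbind, merged)
  }
  runs$width <- runs$end - runs$start + 1L
  runs <- runs[runs$width >= min_width, , drop = FALSE]
  if (!nrow(runs)) return(empty)
  best <- vapply(seq_len(nrow(runs)),
                 function(i) min(fdr[runs$start[i]:runs$end[i]]), 0)
  data.frame(contig = interval$contig,
             start = interval$start + runs$start - 1L,
             end = interval$start + runs$end,
             width = runs$width, best_fdr = best,
             sample = sample_id, stringsAsFactors = FALSE)
}

#' Per-sample de novo footprint discovery
#'
#' Composition of the full per-sample pipeline over a set of analyzed
#' intervals (typically DNase I-hypersensitive sites): bias-aware
#' expected rates, per-nucleotide depletion p-values under the sample's
#' dispersion model, windowed Stouffer combination, empirical FDR against
#' resampled null counts pushed through the identical statistic pipeline
#' (pooled across the interval set), and segmentation into calls.
#'
#' @param profiles list of [cleavage_profile()] objects (one per
#'   analyzed interval).
#' @param genome a `DNAStringSet`.
#' @param bias a `bias_model`.
#' @param model a `dispersion_model`.
#' @param params a [detect_params()] list.
#' @param sample_id sample label.
#' @return list with `stats` (per-interval data frames: obs, exp, p,
#'   tested, stat, fdr), `calls` (pooled footprint call data frame) and
#'   `expected` (list of expected profiles).
#' @export
detect_sample <- function(profiles, genome, bias, model,
                          params = detect_params(), sample_id = "sample") {
  if (inherits(profiles, "cleavage_profile")) profiles <- list(profiles)
  nI <- length(profiles)
  expected <- lapply(profiles, expected_profile, genome = genome,
                     bias = bias, window_half = params$window_half)
  stats_list <- vector("list", nI)
  obs_stats <- vector("list", nI)
  for (i in seq_len(nI)) {
    obs <- profiles[[i]]$counts_plus + profiles[[i]]$counts_minus
    ns <- depletion_pvalue(obs, expected[[i]]$expected, model,
                           min_expected = params$min_expected)
    ns$stat <- windowed_stat(ns$p, ns$tested, params$widths, params$z_cap)
    stats_list[[i]] <- ns
    obs_stats[[i]] <- ns$stat
  }
  null_stats <- .with_seed(params$seed, {
    lapply(seq_len(params$n_null), function(rep) {
      unlist(lapply(seq_len(nI), function(i) {
        y <- sample_null(expected[[i]], model)
        pn <- depletion_pvalue(y$counts_plus + y$counts_minus,
                               expected[[i]]$expected, model,
                               min_expected = params$min_expected)
        windowed_stat(pn$p, pn$tested, params$widths, params$z_cap)
      }))
    })
  })
  fdr_all <- empirical_fdr(unlist(obs_stats), null_stats)
  lens <- lengths(obs_stats)
  offs <- cumsum(c(0L, lens))
  calls <- vector("list", nI)
  for (i in seq_len(nI)) {
    f <- fdr_all[(offs[i] + 1L):offs[i + 1L]]
    stats_list[[i]]$fdr <- f
    cc <- segment_footprints(f, profiles[[i]]$interval,
                             threshold = params$fdr_threshold,
                             merge_gap = params$merge_gap,
                             min_width = params$min_width,
                             sample_id = sample_id)
    calls[[i]] <- refine_boundaries(cc, stats_list[[i]]$obs,
                                    stats_list[[i]]$exp,
                                    stats_list[[i]]$tested,
                                    profiles[[i]]$interval, model,
                                    slack = params$refine_slack)
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  list(stats = stats_list, calls = calls, expected = expected)
}

#' Write footprint calls as BED6+
#'
#' Columns: chrom, start, end, name (`sample:index`), score
#' (`-10*log10(best FDR)` capped at 1000), strand ".", best FDR, width.
#' @param calls call data frame from [detect_sample()].
#' @param path output file.
#' @export
write_footprint_bed <- function(calls, path) {
  score <- pmin(round(-10 * log10(pmax(calls$best_fdr, 1e-100))), 1000)
  score[calls$best_fdr == 0] <- 1000
  df <- data.frame(calls$contig, calls$start, calls$end,
                   sprintf("%s:%d", calls$sample, seq_len(nrow(calls))),
                   score, ".", calls$best_fdr, calls$width)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
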