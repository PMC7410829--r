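#' Two-group design
#'
#' @param samples character vector of sample ids.
#' @param groups character vector of `"A"` / `"B"` labels, one per
#'   sample.
#' @return a data frame of class `group_design`.
#' @export
group_design <- function(samples, groups) {
  stopifnot(length(samples) == length(groups))
  groups <- as.character(groups)
  if (!all(groups %in% c("A", "B")))
    stop("group labels must be 'A' or 'B'")
  if (!any(groups == "A") || !any(groups == "B"))
    stop("both groups must be non-empty")
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  structure(data.frame(sample = as.character(samples), group = groups,
                       stringsAsFactors = FALSE),
            class = c("group_design", "data.frame"))
}

#' Select DHSs testable for differential occupancy
#'
#' Keeps DHSs that are highly accessible — normalized cleavage density at
#' least `min_density` (tags per 150 bp per million reads) — in at least
#' `min_samples` samples of each group.
#'
#' @param density numeric matrix, DHSs x samples, of normalized cleavage
#'   densities; column names are sample ids.
#' @param design a [group_design()].
#' @param min_samples minimum qualifying samples per group (default 10).
#' @param min_density qualifying density threshold (default 1).
#' @return logical vector over rows of `density` (TRUE = testable).
#' @export
select_testable_dhs <- function(density, design, min_samples = 10L,
                                min_density = 1.0) {
  missing <- setdiff(design$sample, colnames(density))
  if (length(missing))
    stop("sample(s) missing from density matrix: ",
         paste(missing, collapse = ", "))
  qa <- rowSums(density[, design$sample[design$group == "A"],
                        drop = FALSE] >= min_density)
  qb <- rowSums(density[, design$sample[design$group == "B"],
                        drop = FALSE] >= min_density)
  qa >= min_samples & qb >= min_samples
}

# profiled NB log-likelihood in phi for a set of samples at one position
.phi_loglik <- function(logphi, y, mu, r) {
  sum(stats::dnbinom(y, size = r, mu = exp(logphi) * mu, log = TRUE))
}

.phi_mle <- function(y, mu, r, bounds = log(c(1e-3, 10)), tol = 1e-7) {
  opt <- stats::optimize(.phi_loglik, interval = bounds, y = y, mu = mu,
                         r = r, maximum = TRUE, tol = tol)
  # optimize can miss a boundary maximum; check the endpoints
  lo <- .phi_loglik(bounds[1], y, mu, r)
  hi <- .phi_loglik(bounds[2], y, mu, r)
  best <- which.max(c(opt$objective, lo, hi))
  phi <- c(opt$maximum, bounds)[best]
  list(phi = exp(phi), ll = c(opt$objective, lo, hi)[best])
}

#' Per-nucleotide differential cleavage test between two groups
#'
#' At each tested position, sample s contributes a negative-binomial
#' likelihood `NB(phi[g(s)] * mu_s, r_s)` where `mu_s` and `r_s` come
#' from the sample's own dispersion model evaluated at its expected
#' rate — the per-sample expected rates act as offsets, so `phi`
#' measures the group-level relative cleavage (depletion) ratio. The
#' likelihood-ratio statistic compares free (phi_A, phi_B) against a
#' shared phi, with p from chi-square (1 df) and BH q across all tested
#' positions.
#'
#' @param obs numeric matrix positions x samples of observed combined
#'   counts; column names are sample ids.
#' @param exp numeric matrix positions x samples of expected rates.
#' @param models named list of per-sample `dispersion_model`s.
#' @param design a [group_design()].
#' @param min_expected per-sample testability threshold (default 0.1).
#' @param min_samples minimum tested samples per group at a position
#'   (default 3).
#' @param phi_bounds search bounds for phi (default \[1e-3, 10\]).
#' @return data frame, one row per position: `phi_A`, `phi_B`,
#'   `phi_shared`, `stat`, `p`, `q`, `tested`.
#' @export
differential_nucleotide_test <- function(obs, exp, models, design,
                                         min_expected = 0.1,
                                         min_samples = 3L,
                                         phi_bounds = c(1e-3, 10)) {
  stopifnot(identical(dim(obs), dim(exp)))
  samples <- colnames(obs)
  if (is.null(samples)) stop("obs matrix needs sample column names")
  if (!all(design$sample %in% samples))
    stop("design samples missing from count matrix")
  obs <- obs[, design$sample, drop = FALSE]
  exp <- exp[, design$sample, drop = FALSE]
  nP <- nrow(obs)
  grpA <- design$group == "A"
  mu <- r <- matrix(NA_real_, nP, ncol(obs))
  for (j in seq_len(ncol(obs))) {
    m <- models[[design$sample[j]]]
    mu[, j] <- mu_fn(m, exp[, j])
    r[, j] <- r_fn(m, exp[, j])
  }
  ok <- is.finite(exp) & exp >= min_expected
  out <- data.frame(phi_A = NA_real_, phi_B = NA_real_,
                    phi_shared = NA_real_, stat = NA_real_,
                    p = NA_real_, q = NA_real_,
                    tested = FALSE)[rep(1, nP), ]
  rownames(out) <- NULL
  lb <- log(phi_bounds)
  for (i in seq_len(nP)) {
    selA <- ok[i, ] & grpA
    selB <- ok[i, ] & !grpA
    if (sum(selA) < min_samples || sum(selB) < min_samples) next
    sel <- selA | selB
    fa <- .phi_mle(obs[i, selA], mu[i, selA], r[i, selA], lb)
    fb <- .phi_mle(obs[i, selB], mu[i, selB], r[i, selB], lb)
    fs <- .phi_mle(obs[i, sel], mu[i, sel], r[i, sel], lb)
    stat <- max(0, 2 * (fa$ll + fb$ll - fs$ll))
    out$phi_A[i] <- fa$phi; out$phi_B[i] <- fb$phi
    out$phi_shared[i] <- fs$phi
    out$stat[i] <- stat
    out$p[i] <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    out$tested[i] <- TRUE
  }
  out$q[out$tested] <- stats::p.adjust(out$p[out$tested], method = "BH")
  out
}

#' Aggregate per-nucleotide differential results to footprints and DHSs
#'
#' A footprint is differential iff it contains at least one position with
#' q at or below `q_cutoff`; a DHS is differential iff it contains at
#' least one differential footprint.
#'
#' @param result data frame from [differential_nucleotide_test()] with an
#'   added `contig`/`pos` pair of columns giving each row's genomic
#'   position (0-based).
#' @param footprints interval data frame of (consensus) footprints.
#' @param dhs interval data frame of the parent DHSs.
#' @param q_cutoff BH q cutoff (default 0.05).
#' @return list with `footprints` (input plus `differential` flag and
#'   `n_sig_positions`) and `dhs` (input plus `differential` and
#'   `n_differential_footprints`).
#' @export
aggregate_differential <- function(result, footprints, dhs,
                                   q_cutoff = 0.05) {
  sig <- result[result$tested & !is.na(result$q) & result$q <= q_cutoff, ,
                drop = FALSE]
  in_iv <- function(iv) {
    vapply(seq_len(nrow(iv)), function(i)
      sum(sig$contig == iv$contig[i] & sig$pos >= iv$start[i] &
            sig$pos < iv$end[i]), 0L)
  }
  footprints$n_sig_positions <- if (nrow(footprints)) in_iv(footprints) else integer()
  footprints$differential <- footprints$n_sig_positions >= 1L
  ndf <- vapply(seq_len(nrow(dhs)), function(i) {
    sel <- footprints$contig == dhs$contig[i] &
      footprints$start >= dhs$start[i] & footprints$end <= dhs$end[i]
    sum(footprints$differential[sel])
  }, 0L)
  dhs$n_differential_footprints <- ndf
  dhs$differential <- ndf >= 1L
  list(footprints = footprints, dhs = dhs)
}
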