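#' Negative-binomial dispersion model of cleavage counts
#'
#' The null model for footprint detection: for one sample, observed
#' per-nucleotide counts given their bias-aware expected rate are treated
#' as negative binomial with a mean and a size (dispersion) parameter that
#' vary smoothly with the expected count. Fitting bins positions by their
#' rounded expected count, estimates NB(mu, r) per bin by maximum
#' likelihood, then smooths the per-bin estimates: a non-negative weighted
#' least-squares line for mu vs expected, and a weighted linear trend of
#' log(r) vs log(1 + expected). Evaluation outside the fitted range is
#' clamped to the range endpoints.
#'
#' @name dispersion_model
NULL

.R_MAX <- 1e8
.R_MIN <- 1e-3

# NB MLE within one bin: the mu MLE is the sample mean for any r, so only
# r needs a 1-D search (method-of-moments start is implicit in the bounds)
.fit_nb_bin <- function(y) {
  m <- mean(y)
  if (m == 0) return(c(mu = 0, r = .R_MAX))
  nll <- function(logr) -sum(stats::dnbinom(y, size = exp(logr),
                                            mu = m, log = TRUE))
  opt <- stats::optimize(nll, interval = log(c(.R_MIN, .R_MAX)), tol = 1e-8)
  c(mu = m, r = exp(opt$minimum))
}

#' Fit the per-sample dispersion model
#'
#' @param observed a [cleavage_profile()] or list of them.
#' @param expected the matching [expected_profile()] (or list). Combined
#'   (plus + minus) counts and rates are used; protection by a bound
#'   factor depletes both strands alike.
#' @param min_positions_per_bin minimum positions per integer expected-
#'   count bin for the bin to enter the fit (default 100).
#' @param min_bins minimum number of usable bins (default 5).
#' @return an object of class `dispersion_model`: trend coefficients, the
#'   fitted range, and the per-bin audit table.
#' @export
fit_dispersion <- function(observed, expected,
                           min_positions_per_bin = 100L, min_bins = 5L) {
  if (inherits(observed, "cleavage_profile")) observed <- list(observed)
  if (inherits(expected, "expected_profile")) expected <- list(expected)
  stopifnot(length(observed) == length(expected))
  obs <- unlist(lapply(observed, function(p) p$counts_plus + p$counts_minus))
  exp_ <- unlist(lapply(expected, function(e) e$expected))
  stopifnot(length(obs) == length(exp_))
  if (all(obs == 0)) stop("all observed counts are zero; cannot fit")
  bin <- round(exp_)
  tab <- table(bin)
  usable <- as.integer(names(tab))[tab >= min_positions_per_bin]
  usable <- usable[usable >= 1L]
  if (length(usable) < min_bins)
    stop(sprintf(
      "need >= %d expected-count bins with >= %d positions; got %d (bin sizes: %s)",
      min_bins, min_positions_per_bin, length(usable),
      paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = " ")))
  fits <- t(vapply(usable, function(n) .fit_nb_bin(obs[bin == n]),
                   c(mu = 0, r = 0)))
  npos <- as.integer(tab[as.character(usable)])
  bin_table <- data.frame(expected_bin = usable, n_positions = npos,
                          mu = fits[, "mu"], r = fits[, "r"])
  # mu trend: weighted LS line, slope forced non-negative
  fm <- stats::lm(mu ~ expected_bin, data = bin_table, weights = npos)
  mu_coef <- stats::coef(fm)
  if (is.na(mu_coef[2]) || mu_coef[2] < 0)
    mu_coef <- c(stats::weighted.mean(bin_table$mu, npos), 0)
  # r trend: weighted line in log r vs log(1 + n); bins driven to the
  # optimizer ceiling (Poisson-like) get reduced weight so a handful of
  # saturated bins cannot dominate the slope
  wr <- npos * ifelse(bin_table$r >= .R_MAX * 0.99, 0.25, 1)
  fr <- stats::lm(log(r) ~ log1p(expected_bin), data = bin_table,
                  weights = wr)
  r_coef <- stats::coef(fr)
  if (any(is.na(r_coef)))
    r_coef <- c(stats::weighted.mean(log(bin_table$r), npos), 0)
  structure(list(mu_coef = unname(mu_coef), r_coef = unname(r_coef),
                 fit_range = range(usable), bin_table = bin_table),
            class = "dispersion_model")
}

#' Evaluate the fitted mean / size trends
#'
#' Expected counts outside the fitted range are clamped to its endpoints.
#' @param model a `dispersion_model`. @param x expected counts.
#' @return numeric vector of fitted means (`mu_fn`) or NB sizes (`r_fn`).
#' @export
mu_fn <- function(model, x) {
  x <- pmin(pmax(x, model$fit_range[1]), model$fit_range[2])
  pmax(model$mu_coef[1] + model$mu_coef[2] * x, 1e-8)
}

#' @rdname mu_fn
#' @export
r_fn <- function(model, x) {
  x <- pmin(pmax(x, model$fit_range[1]), model$fit_range[2])
  pmin(pmax(exp(model$r_coef[1] + model$r_coef[2] * log1p(x)), .R_MIN), .R_MAX)
}

#' @export
print.dispersion_model <- function(x, ...) {
  cat(sprintf("<dispersion_model> %d bins over expected [%g, %g]; mu = %.3g + %.3g*e; r(mid) = %.3g\n",
              nrow(x$bin_table), x$fit_range[1], x$fit_range[2],
              x$mu_coef[1], x$mu_coef[2],
              r_fn(x, mean(x$fit_range))))
  invisible(x)
}

#' Serialize / load a dispersion model
#'
#' TSV bin table preceded by comment lines carrying the trend
#' coefficients and fit range.
#' @param model a `dispersion_model`. @param path file path.
#' @export
write_dispersion_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# mu_coef=%.12g,%.12g", model$mu_coef[1], model$mu_coef[2]),
               sprintf("# r_coef=%.12g,%.12g", model$r_coef[1], model$r_coef[2]),
               sprintf("# fit_range=%g,%g", model$fit_range[1], model$fit_range[2])),
             con)
  suppressWarnings(utils::write.table(model$bin_table, con, sep = "\t",
                                      quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' @rdname write_dispersion_model
#' @export
read_dispersion_model <- function(path) {
  hdr <- readLines(path, n = 3L)
  num <- function(line) as.numeric(strsplit(sub("^# [a-z_]+=", "", line), ",")[[1]])
  bt <- utils::read.delim(path, comment.char = "#")
  structure(list(mu_coef = num(hdr[1]), r_coef = num(hdr[2]),
                 fit_range = num(hdr[3]), bin_table = bt),
            class = "dispersion_model")
}

#' One-sided depletion p-value for observed vs expected counts
#'
#' `p = P(X <= obs)` under `NB(mu_fn(exp), r_fn(exp))` — lower-tail and
#' inclusive of the observed value, hence conservative on discrete
#' counts. Positions with `exp < min_expected` are untested and get the
#' sentinel p = 1 (they can never seed a footprint).
#'
#' @param obs observed counts (vector).
#' @param exp expected rates (vector, same length).
#' @param model a `dispersion_model`.
#' @param min_expected minimum expected rate for a position to be tested
#'   (default 0.1).
#' @return data frame with columns `obs`, `exp`, `p`, `tested`.
#' @export
depletion_pvalue <- function(obs, exp, model, min_expected = 0.1) {
  stopifnot(length(obs) == length(exp))
  tested <- is.finite(exp) & exp >= min_expected
  p <- rep(1, length(obs))
  if (any(tested))
    p[tested] <- stats::pnbinom(obs[tested],
                                size = r_fn(model, exp[tested]),
                                mu = mu_fn(model, exp[tested]))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  data.frame(obs = obs, exp = exp, p = p, tested = tested)
}

#' Sample null counts from the fitted dispersion model
#'
#' Draws an independent NB count at every position of an expected profile
#' (`mu_fn(exp)`, `r_fn(exp)`); positions with zero expected rate draw 0.
#' Used to build the empirical-FDR null: the draws are pushed through the
#' identical statistic pipeline as the observed counts.
#'
#' @param expected an [expected_profile()].
#' @param model a `dispersion_model`.
#' @param seed integer seed for a private RNG stream, or `NULL` to use
#'   the current stream.
#' @return a [cleavage_profile()] holding the combined-strand null draws
#'   in `counts_plus` (`counts_minus` all zero).
#' @export
sample_null <- function(expected, model, seed = NULL) {
  draw <- function() {
    e <- expected$expected
    y <- numeric(length(e))
    pos <- e > 0
    if (any(pos))
      y[pos] <- stats::rnbinom(sum(pos), size = r_fn(model, e[pos]),
                               mu = mu_fn(model, e[pos]))
    y
  }
  y <- if (is.null(seed)) draw() else .with_seed(seed, draw())
  cleavage_profile(expected$interval, y, numeric(length(y)))
}
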