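#' End-to-end detection on a simulated sample
#'
#' Runs the full per-sample pipeline against planted truth: simulate the
#' cohort, learn the hexamer bias table from the simulated profiles
#' themselves, fit the dispersion model, and run de novo footprint
#' detection with the supplied (default) parameters.
#'
#' @param seed integer seed for the simulation.
#' @param spec a [cohort_spec()] (defaults to the benchmark conditions).
#' @param params a [detect_params()]; its seed is derived from `seed`.
#' @param sample_id which simulated sample to analyse (default: first).
#' @return list with `truth`, `calls`, `detection` (full
#'   [detect_sample()] output), `bias`, `model`.
#' @export
run_detection_benchmark <- function(seed, spec = cohort_spec(),
                                    params = NULL, sample_id = NULL) {
  truth <- simulate_truth(spec, seed)
  if (is.null(sample_id)) sample_id <- truth$samples$sample[1]
  sim <- simulate_sample(truth, sample_id, seed + 7919L)
  bias <- build_bias_table(truth$genome, sim$profiles)
  if (is.null(params)) params <- detect_params(seed = seed + 2L * 7919L)
  expected <- lapply(sim$profiles, expected_profile, genome = truth$genome,
                     bias = bias, window_half = params$window_half)
  model <- fit_dispersion(sim$profiles, expected)
  det <- detect_sample(sim$profiles, truth$genome, bias, model,
                       params = params, sample_id = sample_id)
  list(truth = truth, calls = det$calls, detection = det, bias = bias,
       model = model)
}

#' Score footprint calls against planted truth
#'
#' A call is a true positive iff it overlaps at least one planted
#' protected interval (any overlap); a planted footprint is detected iff
#' at least one call overlaps it. For width comparison each detected
#' planted footprint is paired with its maximum-overlap call.
#'
#' @param calls call data frame (`contig`, `start`, `end`, `width`).
#' @param truth_footprints planted footprint data frame (`contig`,
#'   `start`, `end`, ...).
#' @return list: `n_calls`, `n_false`, `fdp` (realized false-discovery
#'   proportion), `sensitivity`, `width_spearman` (rank correlation of
#'   planted vs called width over detected footprints), `pairs` (the
#'   width pairs).
#' @export
evaluate_calls <- function(calls, truth_footprints) {
  tf <- truth_footprints
  if (!nrow(calls))
    return(list(n_calls = 0L, n_false = 0L, fdp = 0,
                sensitivity = 0, width_spearman = NA_real_,
                pairs = data.frame()))
  gc <- as_granges(calls)
  gt <- as_granges(tf)
  ov <- GenomicRanges::findOverlaps(gc, gt)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  is_true <- seq_len(nrow(calls)) %in% qh
  detected <- seq_len(nrow(tf)) %in% sh
  pairs <- data.frame()
  if (length(ov)) {
    inter <- pmin(calls$end[qh], tf$end[sh]) -
      pmax(calls$start[qh], tf$start[sh])
    o <- order(sh, -inter)
    first <- !duplicated(sh[o])
    pairs <- data.frame(truth_width = (tf$end - tf$start)[sh[o][first]],
                        call_width = (calls$end - calls$start)[qh[o][first]])
  }
  ws <- if (nrow(pairs) >= 3L)
    suppressWarnings(stats::cor(pairs$truth_width, pairs$call_width,
                                method = "spearman")) else NA_real_
  list(n_calls = nrow(calls), n_false = sum(!is_true),
       fdp = sum(!is_true) / nrow(calls),
       sensitivity = if (nrow(tf)) mean(detected) else NA_real_,
       width_spearman = ws, pairs = pairs)
}
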