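# brute-force Stouffer oracle: explicit double loop, out-of-range
# positions treated as the capped null
oracle_stouffer <- function(p, widths, z_cap = 8.2) {
  z <- ifelse(p >= 1, z_cap, pmin(qnorm(p), z_cap))
  n <- length(z)
  out <- rep(Inf, n)
  for (i in seq_len(n)) {
    for (w in widths) {
      h <- (w - 1) / 2
      s <- 0
      for (j in (i - h):(i + h))
        s <- s + if (j >= 1 && j <= n) z[j] else z_cap
      out[i] <- min(out[i], s / sqrt(w))
    }
  }
  out
}

# brute-force empirical-FDR oracle with step-up monotonization
oracle_fdr <- function(obs, null_list) {
  R <- length(null_list)
  nul <- unlist(null_list)
  raw <- vapply(obs, function(t)
    min(1, max(0, (sum(nul <= t) / R) / max(1, sum(obs <= t)))), 0)
  out <- vapply(seq_along(obs), function(i)
    min(raw[obs >= obs[i]]), 0)
  out
}

test_that("windowed Stouffer statistic matches hand values and the brute-force oracle", {
  expect_equal(windowed_stat(rep(0.5, 3), widths = 3)[2], 0)
  expect_equal(windowed_stat(rep(0.1, 3), widths = 3)[2],
               3 * qnorm(0.1) / sqrt(3), tolerance = 1e-12)
  # w = 1 is the identity on the z scale
  p <- c(0.2, 0.8, 0.01)
  expect_equal(windowed_stat(p, widths = 1), qnorm(p), tolerance = 1e-12)
  expect_error(windowed_stat(p, widths = 4), "odd")
  set.seed(31)
  for (rep in 1:3) {
    pr <- runif(80)
    pr[sample(80, 5)] <- 1
    got <- windowed_stat(pr, widths = c(3, 5, 9))
    expect_equal(got, oracle_stouffer(pr, c(3, 5, 9)), tolerance = 1e-10)
  }
  # untested positions contribute the capped null z
  pt <- rep(0.1, 5); tested <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  got <- windowed_stat(pt, tested, widths = 3)
  expect_equal(got[3], (2 * qnorm(0.1) + 8.2) / sqrt(3), tolerance = 1e-12)
})

test_that("empirical FDR reproduces direct counting and its edge cases", {
  # self-null: every position at FDR 1
  obs <- c(-2, -1, 0, 1)
  expect_equal(empirical_fdr(obs, list(obs)), rep(1, 4))
  # direct counting example
  got <- empirical_fdr(c(-5, -1, 0), list(c(-0.5, 0, 0.2)))
  expect_equal(got, c(0, 0, 2 / 3), tolerance = 1e-12)
  # all-positive observed against a standard normal null: nothing called
  set.seed(32)
  got2 <- empirical_fdr(runif(100, 1, 3), list(rnorm(100)))
  expect_gte(min(got2), 0.8)
  # randomized agreement with the brute-force oracle, multiple replicates
  for (rep in 1:3) {
    o <- rnorm(60)
    nl <- list(rnorm(60), rnorm(60), rnorm(60))
    expect_equal(empirical_fdr(o, nl), oracle_fdr(o, nl), tolerance = 1e-10)
  }
  expect_error(empirical_fdr(obs, list()), "replicate")
})

test_that("FDR is monotone in the statistic after step-up monotonization", {
  set.seed(33)
  o <- rnorm(200)
  f <- empirical_fdr(o, list(rnorm(200)))
  ord <- order(o)
  expect_true(all(diff(f[ord]) >= 0))
  expect_true(all(f >= 0 & f <= 1))
})

test_that("segmentation forms, merges and filters runs correctly", {
  iv <- genomic_interval("c1", 100, 105)
  calls <- segment_footprints(c(1, .005, .005, .005, 1), iv,
                              threshold = 0.01, merge_gap = 0, min_width = 3)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$start, 101)
  expect_equal(calls$end, 104)
  expect_equal(calls$width, 3)
  expect_equal(calls$best_fdr, 0.005)

  expect_equal(nrow(segment_footprints(rep(1, 10),
                                       genomic_interval("c1", 0, 10),
                                       threshold = 0.01)), 0)

  # two width-3 runs separated by 2 failing positions merge at gap 3
  fdr <- c(rep(.001, 3), 1, 1, rep(.001, 3))
  iv2 <- genomic_interval("c1", 0, 8)
  m <- segment_footprints(fdr, iv2, threshold = .01, merge_gap = 3,
                          min_width = 3)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(0, 8))
  # but not at gap 1
  m2 <- segment_footprints(fdr, iv2, threshold = .01, merge_gap = 1,
                           min_width = 3)
  expect_equal(nrow(m2), 2)
  # min_width filters short runs after merging
  m3 <- segment_footprints(c(.001, .001, 1, 1, 1, 1),
                           genomic_interval("c1", 0, 6),
                           threshold = .01, merge_gap = 0, min_width = 3)
  expect_equal(nrow(m3), 0)
})

test_that("a planted footprint is recovered with tight boundaries", {
  g <- random_genome(1200, seed = 34)
  iv <- genomic_interval("c1", 100, 1100)
  w <- interval_width(iv)
  mdl <- manual_model(r = 8)
  set.seed(35)
  lam <- rep(20, w)
  fp <- 401:415 - 100       # planted 0-based [401, 416), width 15, delta 0.2
  lam[fp] <- 4
  obs <- rnbinom(w, size = 8, mu = lam)
  cp <- cleavage_profile(iv, obs, numeric(w))
  det <- detect_sample(cp, g, uniform_bias_model(), mdl,
                       params = detect_params(n_null = 20, seed = 36))
  expect_equal(nrow(det$calls), 1)
  expect_lte(abs(det$calls$start - 401), 3)
  expect_lte(abs(det$calls$end - 416), 3)
})

test_that("null intervals yield no calls at the 1% threshold in most seeds", {
  g <- random_genome(700, seed = 37)
  iv <- genomic_interval("c1", 100, 600)
  w <- interval_width(iv)
  mdl <- manual_model(r = 8)
  n_calls <- integer(40)
  set.seed(38)
  for (s in seq_along(n_calls)) {
    obs <- rnbinom(w, size = 8, mu = 20)
    cp <- cleavage_profile(iv, obs, numeric(w))
    det <- detect_sample(cp, g, uniform_bias_model(), mdl,
                         params = detect_params(n_null = 5, seed = 1000 + s))
    n_calls[s] <- nrow(det$calls)
  }
  expect_gte(mean(n_calls == 0), 0.95)
})

test_that("zero-depth intervals are untested everywhere and yield no calls", {
  g <- random_genome(600, seed = 39)
  iv <- genomic_interval("c1", 100, 500)
  w <- interval_width(iv)
  cp <- cleavage_profile(iv, numeric(w), numeric(w))
  det <- detect_sample(cp, g, uniform_bias_model(), manual_model(8),
                       params = detect_params(seed = 40))
  expect_equal(nrow(det$calls), 0)
  expect_false(any(det$stats[[1]]$tested))
})

test_that("sensitivity rises with sequencing depth on fixed truth", {
  spec_at <- function(d) cohort_spec(genome_length = 1e5, n_dhs = 30,
                                     depth = c(d, d),
                                     depletion = c(0.25, 0.35))
  sens <- vapply(c(3, 12, 40), function(d) {
    bm <- suppressWarnings(run_detection_benchmark(5, spec_at(d)))
    evaluate_calls(bm$calls, bm$truth$footprints)$sensitivity
  }, 0)
  expect_true(all(diff(sens) >= 0))
  expect_gt(sens[3], 0.8)
})

test_that("footprint BED output encodes score and extra columns", {
  calls <- data.frame(contig = "c1", start = c(10L, 50L), end = c(20L, 60L),
                      width = c(10L, 10L), best_fdr = c(0.001, 0),
                      sample = "s1", stringsAsFactors = FALSE)
  d <- withr::local_tempdir()
  f <- file.path(d, "fp.bed")
  write_footprint_bed(calls, f)
  lines <- read.delim(f, header = FALSE)
  expect_equal(lines$V5, c(30, 1000))
  expect_equal(lines$V8, c(10, 10))
})
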