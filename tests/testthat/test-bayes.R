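test_that("the cross-sample prior follows the Laplace formula", {
  iv <- genomic_interval("c1", 0, 10)
  mkcalls <- function(n_cover) {
    lapply(seq_len(10), function(i) {
      if (i <= n_cover)
        data.frame(contig = "c1", start = 0L, end = 10L)
      else data.frame(contig = character(), start = integer(),
                      end = integer())
    })
  }
  expect_equal(footprint_prior(mkcalls(0), iv), rep(1 / 12, 10))
  expect_equal(footprint_prior(mkcalls(10), iv), rep(11 / 12, 10))
  expect_equal(footprint_prior(mkcalls(3), iv), rep(4 / 12, 10))
  # partial coverage counts per position
  calls <- c(list(data.frame(contig = "c1", start = 0L, end = 5L)),
             mkcalls(0)[1:9])
  pr <- footprint_prior(calls, iv)
  expect_equal(pr[1:5], rep(2 / 12, 5))
  expect_equal(pr[6:10], rep(1 / 12, 5))
})

test_that("occupancy likelihoods separate protected from unprotected counts", {
  mdl <- manual_model(r = 20)
  l <- occupancy_likelihoods(40, 40, mdl)
  expect_gt(l$L_unocc, l$L_occ)
  l0 <- occupancy_likelihoods(0, 40, mdl)
  expect_gt(l0$L_occ / l0$L_unocc, 1e3)
  # degenerate grid {1} makes the two likelihoods identical
  ld <- occupancy_likelihoods(c(0, 10, 40), rep(40, 3), mdl,
                              depletion_grid = 1)
  expect_equal(ld$L_occ, ld$L_unocc)
  # untested sentinel
  lu <- occupancy_likelihoods(1, 0.01, mdl)
  expect_false(lu$tested)
  expect_true(is.na(lu$L_occ))
})

# evidence_half = 0: the exact per-position Bayes update, so pointwise
# properties can be asserted independently of the evidence window
mk_track <- function(obs, expv, prior, r = 20, evidence_half = 0L) {
  n <- length(obs)
  iv <- genomic_interval("c1", 0, n)
  cp <- cleavage_profile(iv, obs, numeric(n))
  ep <- structure(list(interval = iv, expected = expv,
                       expected_plus = expv / 2, expected_minus = expv / 2,
                       window_half = 50L), class = "expected_profile")
  posterior_track(cp, ep, manual_model(r = r), prior,
                  evidence_half = evidence_half)
}

test_that("the posterior behaves as Bayes' rule demands", {
  # prior 0 pins the posterior at 0 whatever the counts
  t0 <- mk_track(c(0, 0), c(40, 40), c(0, 0))
  expect_equal(t0$posterior, c(0, 0))
  # fully protected deep position with a moderate prior is near-certain
  t1 <- mk_track(0, 40, 1 / 3)
  expect_gt(t1$posterior, 0.99)
  # counts at expectation argue against protection
  t2 <- mk_track(40, 40, 0.5)
  expect_lt(t2$posterior, 0.5)
  # monotone decreasing in obs at fixed prior
  tm <- mk_track(0:40, rep(40, 41), rep(0.3, 41))
  expect_true(all(diff(tm$posterior) < 1e-12))
  # monotone increasing in prior at fixed counts
  tp <- mk_track(rep(5, 9), rep(40, 9), seq(0.1, 0.9, by = 0.1))
  expect_true(all(diff(tp$posterior) > 0))
  # untested positions inherit the prior
  tu <- mk_track(0, 0.01, 0.3)
  expect_equal(tu$posterior, 0.3)
  expect_false(tu$tested)
  # windowless posterior is the exact plug-in of the per-position
  # likelihoods
  l <- occupancy_likelihoods(5, 40, manual_model(r = 20))
  expect_equal(mk_track(5, 40, 0.3)$posterior,
               0.3 * l$L_occ / (0.3 * l$L_occ + 0.7 * l$L_unocc),
               tolerance = 1e-12)
})

test_that("high-posterior segments are maximal runs above the cutoff", {
  tr <- mk_track(c(30, 0, 0, 30), rep(30, 4), rep(0.5, 4))
  tr$posterior <- c(0.5, 0.995, 0.999, 0.2)   # frozen track
  seg <- sample_segments(tr, cutoff = 0.99)
  expect_equal(nrow(seg), 1)
  expect_equal(c(seg$start, seg$end), c(1, 3))
  tr$posterior <- rep(0.5, 4)
  expect_equal(nrow(sample_segments(tr, 0.99)), 0)
  tr$posterior <- rep(0.999, 4)
  seg2 <- sample_segments(tr, 0.99)
  expect_equal(c(seg2$start, seg2$end), c(0, 4))
})

test_that("consensus collation is idempotent, median-bounded and order-invariant", {
  one <- data.frame(contig = "c1", start = c(10L, 40L), end = c(20L, 55L),
                    sample = "s1", stringsAsFactors = FALSE)
  ci <- consensus_index(one)
  expect_equal(ci$footprints$start, one$start)
  expect_equal(ci$footprints$end, one$end)
  expect_equal(ci$footprints$n_samples, c(1L, 1L))

  five <- do.call(rbind, lapply(sprintf("s%d", 1:5), function(s)
    data.frame(contig = "c1", start = 10L, end = 20L, sample = s,
               stringsAsFactors = FALSE)))
  cf <- consensus_index(five)$footprints
  expect_equal(nrow(cf), 1)
  expect_equal(c(cf$start, cf$end, cf$n_samples), c(10, 20, 5))

  stag <- data.frame(contig = "c1", start = c(10L, 12L, 14L),
                     end = c(20L, 22L, 24L),
                     sample = sprintf("s%d", 1:3), stringsAsFactors = FALSE)
  cs <- consensus_index(stag)$footprints
  expect_equal(nrow(cs), 1)
  expect_equal(c(cs$start, cs$end, cs$n_samples), c(12, 22, 3))

  # even member count: lower-median start, upper-median end
  ev <- data.frame(contig = "c1", start = c(10L, 12L, 14L, 16L),
                   end = c(20L, 22L, 24L, 26L),
                   sample = sprintf("s%d", 1:4), stringsAsFactors = FALSE)
  ce <- consensus_index(ev)$footprints
  expect_equal(c(ce$start, ce$end), c(12, 24))

  # input order never changes the result
  set.seed(41)
  segs <- data.frame(
    contig = "c1",
    start = sample(0:500, 60, replace = TRUE),
    sample = sample(sprintf("s%d", 1:6), 60, replace = TRUE),
    stringsAsFactors = FALSE)
  segs$end <- segs$start + sample(8:25, 60, replace = TRUE)
  base <- consensus_index(segs)$footprints
  for (rep in 1:3) {
    perm <- segs[sample(nrow(segs)), ]
    expect_equal(consensus_index(perm)$footprints, base)
  }
  # support always equals the distinct member samples
  ci2 <- consensus_index(segs)
  audit <- tapply(ci2$members$sample, ci2$members$id,
                  function(s) length(unique(s)))
  expect_equal(as.vector(audit[ci2$footprints$id]),
               ci2$footprints$n_samples)
})

test_that("motif assignment applies the 90% overlap rule and ranks by score", {
  fps <- data.frame(contig = "c1", start = c(98L, 105L), end = c(115L, 130L),
                    id = c("f1", "f2"), stringsAsFactors = FALSE)
  hits <- data.frame(contig = "c1", start = c(100L, 100L, 99L),
                     end = c(112L, 112L, 113L),
                     motif = c("M1", "M2", "M3"),
                     score = c(6.4, 8.1, 5.0),
                     strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  res <- assign_motifs(fps, hits, min_overlap_frac = 0.9)
  f1 <- res$assignments[res$assignments$id == "f1", ]
  # f1 contains all three motifs fully (or >= 90%): ranked by score
  expect_equal(f1$motif, c("M2", "M1", "M3"))
  expect_equal(f1$rank, 1:3)
  expect_equal(res$footprints$class, c("ranked", "unassigned"))
  # f2 overlaps motif [100,112) by only 7/12 < 0.9
  expect_false("f2" %in% res$assignments$id)
})

test_that("posterior-integrated footprints agree across replicates at least as well as de novo calls", {
  spec <- cohort_spec(n_samples = c(A = 2L, B = 0L), genome_length = 1e5,
                      n_dhs = 30, depletion = c(0.15, 0.35))
  cohort <- simulate_cohort(spec, 55)
  truth <- cohort$truth
  sims <- cohort$samples
  dets <- list(); models <- list(); biases <- list()
  for (sid in names(sims)) {
    bias <- suppressWarnings(build_bias_table(truth$genome,
                                              sims[[sid]]$profiles))
    expl <- lapply(sims[[sid]]$profiles, expected_profile,
                   genome = truth$genome, bias = bias)
    mdl <- fit_dispersion(sims[[sid]]$profiles, expl)
    dets[[sid]] <- detect_sample(sims[[sid]]$profiles, truth$genome, bias,
                                 mdl, params = detect_params(seed = 56),
                                 sample_id = sid)
    models[[sid]] <- mdl
    biases[[sid]] <- bias
  }
  denovo_j <- jaccard_bp(dets[[1]]$calls, dets[[2]]$calls)
  segs <- list()
  for (sid in names(sims)) {
    out <- list()
    for (i in seq_len(nrow(truth$dhs))) {
      iv <- genomic_interval(truth$dhs$contig[i], truth$dhs$start[i],
                             truth$dhs$end[i])
      pr <- footprint_prior(lapply(dets, function(d) d$calls), iv)
      tr <- posterior_track(sims[[sid]]$profiles[[i]],
                            dets[[sid]]$expected[[i]], models[[sid]], pr,
                            sample_id = sid)
      out[[i]] <- sample_segments(tr, 0.99)
    }
    segs[[sid]] <- do.call(rbind, out)
  }
  # collation snaps overlapping segments to shared consensus bounds: the
  # consensus footprints supported by each replicate agree better than
  # the replicates' independent de novo calls
  ci <- consensus_index(rbind(segs[[1]], segs[[2]]))
  per_rep <- lapply(names(sims), function(sid) {
    ids <- unique(ci$members$id[ci$members$sample == sid])
    ci$footprints[ci$footprints$id %in% ids, ]
  })
  bayes_j <- jaccard_bp(per_rep[[1]], per_rep[[2]])
  expect_gte(bayes_j, denovo_j)
  expect_gt(bayes_j, 0.5)
})
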