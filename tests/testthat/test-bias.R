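# independent tally oracle: direct substring loop over every position
oracle_bias <- function(genome, profile, k = 6, offset = 3) {
  seqc <- as.character(genome[[profile$interval$contig]])
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  occ <- numeric(0); cle <- numeric(0)
  add <- function(m, n) {
    if (!m %in% names(occ)) { occ[m] <<- 0; cle[m] <<- 0 }
    occ[m] <<- occ[m] + 1
    cle[m] <<- cle[m] + n
  }
  for (i in seq.int(profile$interval$start, profile$interval$end - 1)) {
    lo <- i - offset + 1; hi <- i - offset + k          # 1-based plus window
    if (lo >= 1 && hi <= nchar(seqc)) {
      m <- substr(seqc, lo, hi)
      if (!grepl("N", m)) add(m, profile$counts_plus[i - profile$interval$start + 1])
    }
    lo2 <- i - (k - 1 - offset) + 1; hi2 <- i + offset + 1
    if (lo2 >= 1 && hi2 <= nchar(seqc)) {
      m2 <- substr(seqc, lo2, hi2)
      if (!grepl("N", m2)) add(revcomp(m2),
                               profile$counts_minus[i - profile$interval$start + 1])
    }
  }
  pref <- pmax((cle / occ) / (sum(cle) / sum(occ)), 1e-3)
  pref / mean(pref)
}

test_that("uniform per-occurrence cleavage yields preference 1 everywhere", {
  g <- random_genome(4000, seed = 1)
  iv <- genomic_interval("c1", 10, 3990)
  w <- interval_width(iv)
  cp <- cleavage_profile(iv, rep(2, w), rep(2, w))
  b <- suppressWarnings(build_bias_table(g, cp))
  obs <- b$pref[!is.na(b$pref)]
  expect_true(all(abs(obs - 1) < 1e-12))
})

test_that("bias table matches the direct ratio-of-rates tally oracle", {
  g <- random_genome(3000, seed = 2)
  iv <- genomic_interval("c1", 20, 2980)
  w <- interval_width(iv)
  set.seed(3)
  cp <- cleavage_profile(iv, rpois(w, 3), rpois(w, 3))
  b <- suppressWarnings(build_bias_table(g, cp))
  orc <- oracle_bias(g, cp)
  shared <- intersect(names(orc), names(b$pref)[!is.na(b$pref)])
  expect_gt(length(shared), 1000)
  expect_equal(unname(b$pref[shared]), unname(orc[shared]), tolerance = 1e-9)
  # contexts doubled in rate come out with ~2x preference
  expect_equal(mean(b$pref[!is.na(b$pref)]), 1, tolerance = 1e-12)
})

test_that("a context cut at twice the mean rate gets preference ~2", {
  g <- random_genome(6000, seed = 4)
  iv <- genomic_interval("c1", 10, 5990)
  w <- interval_width(iv)
  seqc <- as.character(g[["c1"]])
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  # plus-strand context of position i is seq[i-3 .. i+2] (0-based);
  # minus-strand context is revcomp(seq[i-2 .. i+3])
  pos0 <- seq.int(iv$start, iv$end - 1)
  ctx_p <- vapply(pos0, function(i) substr(seqc, i - 2, i + 3), "")
  ctx_m <- vapply(pos0, function(i) revcomp(substr(seqc, i - 1, i + 4)), "")
  target <- names(sort(table(c(ctx_p, ctx_m)), decreasing = TRUE))[1]
  cp <- cleavage_profile(iv, ifelse(ctx_p == target, 2, 1),
                         ifelse(ctx_m == target, 2, 1))
  b <- suppressWarnings(build_bias_table(g, cp))
  expect_equal(unname(b$pref[target]), 2, tolerance = 0.01)
})

test_that("positions whose context contains N are excluded from the tally", {
  d <- withr::local_tempdir()
  fa <- file.path(d, "g.fa")
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  substr(s, 250, 250) <- "N"
  writeLines(c(">c1", s), fa)
  g <- read_genome(fa)
  iv <- genomic_interval("c1", 10, 490)
  w <- interval_width(iv)
  cp <- cleavage_profile(iv, rep(1, w), rep(1, w))
  b <- suppressWarnings(build_bias_table(g, cp))
  # N at 0-based 249 blots out plus contexts of positions 246..252
  expect_equal(b$total_contexts, 2 * w - 2 * 6)
})

test_that("expected profile reduces to a windowed mean under uniform bias", {
  g <- random_genome(400, seed = 6)
  iv <- genomic_interval("c1", 50, 350)
  w <- interval_width(iv)
  set.seed(7)
  obs <- rpois(w, 5)
  cp <- cleavage_profile(iv, obs, numeric(w))
  e <- expected_profile(cp, g, uniform_bias_model(), window_half = 10)
  # interior positions: centered moving average
  csum <- c(0, cumsum(obs))
  i <- 50
  expect_equal(e$expected_plus[i], (csum[i + 11] - csum[i - 10]) / 21)
  expect_equal(e$expected_minus, rep(0, w))
  expect_equal(e$expected, e$expected_plus)
})

test_that("observed mass is redistributed in proportion to context preference", {
  # 5-position toy: single window spanning all, b = [1,1,2,1,1]
  d <- withr::local_tempdir()
  fa <- file.path(d, "g.fa")
  writeLines(c(">c1", "ACGTACGTACG"), fa)
  g <- read_genome(fa)
  iv <- genomic_interval("c1", 3, 8)
  bias <- uniform_bias_model()
  # plus context of 0-based position 5 is seq[2..7] = "GTACGT"
  bias$pref["GTACGT"] <- 2
  cp <- cleavage_profile(iv, c(0, 10, 0, 0, 0), rep(0, 5))
  e <- expected_profile(cp, g, bias, window_half = 4)
  expect_equal(e$expected_plus,
               c(10 / 6, 10 / 6, 20 / 6, 10 / 6, 10 / 6), tolerance = 1e-12)
})

test_that("expected profile conserves mass, scales with counts, ignores bias scale", {
  g <- random_genome(1000, seed = 8)
  iv <- genomic_interval("c1", 100, 700)
  w <- interval_width(iv)
  set.seed(9)
  cp <- cleavage_profile(iv, rpois(w, 4), rpois(w, 3))
  bias <- random_bias_model(seed = 10)
  # window spanning the whole interval: totals conserved per strand
  e <- expected_profile(cp, g, bias, window_half = w)
  expect_equal(sum(e$expected_plus), sum(cp$counts_plus), tolerance = 1e-9)
  expect_equal(sum(e$expected_minus), sum(cp$counts_minus), tolerance = 1e-9)
  # scale equivariance in the counts
  cp3 <- cleavage_profile(iv, 3 * cp$counts_plus, 3 * cp$counts_minus)
  e3 <- expected_profile(cp3, g, bias, window_half = 25)
  e1 <- expected_profile(cp, g, bias, window_half = 25)
  expect_equal(e3$expected, 3 * e1$expected, tolerance = 1e-12)
  # invariance under rescaling of all preferences
  bias2 <- bias
  bias2$pref <- bias2$pref * 7
  e2 <- expected_profile(cp, g, bias2, window_half = 25)
  expect_equal(e2$expected, e1$expected, tolerance = 1e-12)
  # all-zero observed gives all-zero expected
  e0 <- expected_profile(cleavage_profile(iv, numeric(w), numeric(w)),
                         g, bias, window_half = 25)
  expect_true(all(e0$expected == 0))
})

test_that("bias table serialization round-trips", {
  d <- withr::local_tempdir()
  b <- random_bias_model(seed = 11)
  f <- file.path(d, "bias.tsv")
  write_bias_table(b, f)
  b2 <- read_bias_table(f)
  expect_equal(b2$k, b$k)
  expect_equal(b2$offset, b$offset)
  expect_equal(b2$pref, b$pref, tolerance = 1e-9)
})
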