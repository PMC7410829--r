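#' Hexamer cleavage-preference model
#'
#' DNase I cuts DNA with a slight but reproducible sequence preference.
#' fpkit models it as a relative rate per k-mer context around the cleaved
#' base: `offset` bases of the k-mer lie 5' of the cleaved base on the
#' cleaved strand (default k = 6, offset = 3: three 5' bases, the cleaved
#' base, two 3' bases). Minus-strand cleavages are tallied against the
#' reverse-complement context so one table serves both strands.
#'
#' @name bias_model
NULL

.BASES <- c("A", "C", "G", "T")

# integer encoding A=0 C=1 G=2 T=3, NA for anything else (N)
.encode_chr <- local({
  tab <- rep(NA_integer_, 256)
  tab[utf8ToInt("A")] <- 0L; tab[utf8ToInt("C")] <- 1L
  tab[utf8ToInt("G")] <- 2L; tab[utf8ToInt("T")] <- 3L
  function(s) tab[utf8ToInt(s)]
})

# x[i + shift] with NA outside [1, n]
.shift <- function(x, shift) {
  n <- length(x)
  i <- seq_len(n) + shift
  out <- rep(NA_integer_, n)
  ok <- i >= 1L & i <= n
  out[ok] <- x[i[ok]]
  out
}

# 1-based k-mer index (1..4^k) of the plus-strand context at every
# position of an encoded contig; NA where the window leaves the contig or
# contains N. Minus contexts are the reverse complement of the window
# [i-(k-1-offset), i+offset].
.context_index <- function(code, k, offset, strand = c("+", "-")) {
  strand <- match.arg(strand)
  idx <- rep(0, length(code))
  for (j in 0:(k - 1L)) {
    if (strand == "+") {
      v <- .shift(code, j - offset)
    } else {
      v <- 3L - .shift(code, offset - j)
    }
    idx <- idx * 4 + v
  }
  as.integer(idx + 1L)
}

.all_kmers <- function(k) {
  g <- do.call(expand.grid,
               rev(replicate(k, .BASES, simplify = FALSE)))
  apply(g[, rev(seq_len(k)), drop = FALSE], 1, paste0, collapse = "")
}

#' Learn the k-mer cleavage-preference table
#'
#' For every k-mer context m the relative preference is the ratio of its
#' per-occurrence cleavage rate to the overall per-occurrence rate:
#' `pref(m) = (cleavages in context m / occurrences of m) /
#' (total cleavages / total contexts)`, afterwards rescaled so the mean
#' preference over observed k-mers is exactly 1. Plus-strand cleavages are
#' tallied against the forward context, minus-strand cleavages against the
#' reverse-complement context. Contexts containing N or truncated by a
#' contig end are skipped.
#'
#' @param genome a `DNAStringSet` from [read_genome()].
#' @param profiles a list of [cleavage_profile()] objects.
#' @param k context width (default 6).
#' @param offset 0-based index of the cleaved base within the k-mer
#'   (default 3).
#' @param min_pref positive floor applied to the raw preference ratio
#'   before normalization (default 1e-3), so k-mers observed without any
#'   cleavage keep a small positive rate instead of zeroing the expected
#'   profile wherever they occur.
#' @return an object of class `bias_model` with elements `k`, `offset`,
#'   `pref` (numeric vector of length `4^k`, NA for unobserved k-mers) and
#'   tally totals.
#' @export
build_bias_table <- function(genome, profiles, k = 6L, offset = 3L,
                             min_pref = 1e-3) {
  stopifnot(k >= 1L, offset >= 0L, offset < k)
  if (inherits(profiles, "cleavage_profile")) profiles <- list(profiles)
  if (!length(profiles)) stop("no cleavage profiles supplied")
  nk <- 4L^k
  occ <- numeric(nk)
  cle <- numeric(nk)
  for (pf in profiles) {
    iv <- pf$interval
    for (st in c("+", "-")) {
      idx <- .context_slice(genome, iv$contig, iv$start, iv$end,
                            k, offset, st)
      cnt <- if (st == "+") pf$counts_plus else pf$counts_minus
      ok <- !is.na(idx)
      occ <- occ + tabulate(idx[ok], nbins = nk)
      has <- ok & cnt > 0
      if (any(has)) {
        rs <- rowsum(cnt[has], idx[has])
        at <- as.integer(rownames(rs))
        cle[at] <- cle[at] + rs[, 1]
      }
    }
  }
  total_cle <- sum(cle)
  total_occ <- sum(occ)
  if (total_cle < nk * 10)
    warning(sprintf("only %g cleavages tallied; < %d (4^k x 10) recommended",
                    total_cle, nk * 10L))
  if (total_cle == 0) stop("no cleavage events in supplied profiles")
  observed <- occ > 0
  if (any(!observed))
    warning(sprintf("%d k-mers with zero occurrences excluded",
                    sum(!observed)))
  pref <- rep(NA_real_, nk)
  pref[observed] <- pmax((cle[observed] / occ[observed]) /
                           (total_cle / total_occ), min_pref)
  pref[observed] <- pref[observed] / mean(pref[observed])
  names(pref) <- .all_kmers(k)
  structure(list(k = as.integer(k), offset = as.integer(offset),
                 pref = pref, total_cleavages = total_cle,
                 total_contexts = total_occ),
            class = "bias_model")
}

#' A flat (uniform) bias model
#' @param k context width; @param offset cleaved-base index.
#' @return a `bias_model` with every preference 1.
#' @export
uniform_bias_model <- function(k = 6L, offset = 3L) {
  pref <- rep(1, 4L^k)
  names(pref) <- .all_kmers(k)
  structure(list(k = as.integer(k), offset = as.integer(offset),
                 pref = pref, total_cleavages = NA_real_,
                 total_contexts = NA_real_),
            class = "bias_model")
}

#' @export
print.bias_model <- function(x, ...) {
  ob <- sum(!is.na(x$pref))
  cat(sprintf("<bias_model> k=%d offset=%d, %d/%d k-mers observed, pref range [%.3g, %.3g]\n",
              x$k, x$offset, ob, length(x$pref),
              min(x$pref, na.rm = TRUE), max(x$pref, na.rm = TRUE)))
  invisible(x)
}

#' Serialize / load a bias model as TSV
#'
#' Two columns (`kmer`, `preference`); header comment lines record k,
#' offset and tally sizes.
#' @param model a `bias_model`. @param path file path.
#' @return `path` (write) or a `bias_model` (read).
#' @export
write_bias_table <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# k=%d offset=%d", model$k, model$offset),
               sprintf("# total_cleavages=%g total_contexts=%g",
                       model$total_cleavages, model$total_contexts),
               "kmer\tpreference"), con)
  ok <- !is.na(model$pref)
  writeLines(sprintf("%s\t%.10g", names(model$pref)[ok], model$pref[ok]), con)
  invisible(path)
}

#' @rdname write_bias_table
#' @export
read_bias_table <- function(path) {
  hdr <- readLines(path, n = 2L)
  k <- as.integer(sub(".*k=(\\d+).*", "\\1", hdr[1]))
  offset <- as.integer(sub(".*offset=(\\d+).*", "\\1", hdr[1]))
  num_or_na <- function(s) if (s == "NA") NA_real_ else as.numeric(s)
  tc <- num_or_na(sub(".*total_cleavages=([0-9.eENA+-]+) .*", "\\1", hdr[2]))
  to <- num_or_na(sub(".*total_contexts=([0-9.eENA+-]+).*", "\\1", hdr[2]))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  pref <- rep(NA_real_, 4L^k)
  names(pref) <- .all_kmers(k)
  pref[df$kmer] <- df$preference
  structure(list(k = k, offset = offset, pref = pref,
                 total_cleavages = tc, total_contexts = to),
            class = "bias_model")
}

# k-mer context indices for positions [start, end) of a contig, computed
# on a local sequence slice (plus k bp margins) so the cost is O(width)
.context_slice <- function(genome, contig, start, end, k, offset, strand) {
  len <- Biostrings::width(genome[match(contig, names(genome))])
  s0 <- start - k                      # wanted slice, 0-based half-open
  e0 <- end + k
  a0 <- max(0L, s0)
  a1 <- min(len, e0)
  code <- .encode_chr(as.character(Biostrings::subseq(genome[[contig]],
                                                      a0 + 1L, a1)))
  # NA-pad where the slice leaves the contig so edge windows stay
  # unresolvable, exactly as with a whole-contig scan
  code <- c(rep(NA_integer_, a0 - s0), code, rep(NA_integer_, e0 - a1))
  idx_all <- .context_index(code, k, offset, strand)
  idx_all[(start - s0 + 1L):(start - s0 + (end - start))]
}

# per-position bias values for one strand over an interval; unresolvable
# contexts (N, contig edge, k-mer unobserved in training) get 1
.bias_values <- function(genome, interval, bias, strand) {
  idx <- .context_slice(genome, interval$contig, interval$start,
                        interval$end, bias$k, bias$offset, strand)
  b <- rep(1, length(idx))
  ok <- !is.na(idx)
  v <- bias$pref[idx[ok]]
  v[is.na(v)] <- 1
  b[ok] <- v
  b
}

# sliding-window sum with windows truncated at the array ends
.winsum <- function(x, half) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  cs[hi + 1L] - cs[lo]
}

#' Bias-aware expected cleavage rates
#'
#' Redistributes the observed cleavage mass of a smoothing window across
#' its positions in proportion to each position's context preference:
#' per strand, `expected[i] = winsum(observed) * b[i] / winsum(b)` over a
#' centred window of half-width `window_half` (truncated at the interval
#' ends). When the window spans the whole interval the expected profile
#' conserves the observed total exactly. Uniform preferences reduce the
#' expected rate to a windowed mean of the observed counts.
#'
#' @param observed a [cleavage_profile()].
#' @param genome a `DNAStringSet`.
#' @param bias a `bias_model`.
#' @param window_half smoothing half-width in bp (default 50, i.e. a
#'   101-bp window).
#' @return an object of class `expected_profile` with `expected_plus`,
#'   `expected_minus` and their sum `expected`.
#' @export
expected_profile <- function(observed, genome, bias, window_half = 50L) {
  interval <- observed$interval
  w <- interval_width(interval)
  if (window_half < 1L) stop("window_half must be >= 1")
  ep <- em <- numeric(w)
  for (st in c("+", "-")) {
    b <- .bias_values(genome, interval, bias, st)
    cnt <- if (st == "+") observed$counts_plus else observed$counts_minus
    num <- .winsum(cnt, window_half) * b
    den <- .winsum(b, window_half)
    e <- ifelse(den > 0, num / den, 0)
    if (st == "+") ep <- e else em <- e
  }
  structure(list(interval = interval, expected_plus = ep,
                 expected_minus = em, expected = ep + em,
                 window_half = as.integer(window_half)),
            class = "expected_profile")
}

#' Estimate the depletion ratio of candidate footprints
#'
#' For each candidate interval, the depletion ratio is the total observed
#' count inside the interval divided by the background expectation for
#' those positions. The background is computed like [expected_profile()]
#' but with all candidate-interval positions masked out of the smoothing
#' window, so the estimate is not dragged down by the protection it is
#' measuring.
#'
#' @param observed a [cleavage_profile()].
#' @param genome a `DNAStringSet`.
#' @param bias a `bias_model`.
#' @param candidates interval data frame of candidate footprints (must
#'   lie within the profile's interval).
#' @param window_half smoothing half-width (default 50).
#' @return `candidates` with an added `delta_hat` column.
#' @export
estimate_depletion <- function(observed, genome, bias, candidates,
                               window_half = 50L) {
  iv <- observed$interval
  w <- interval_width(iv)
  obs <- observed$counts_plus + observed$counts_minus
  bp <- .bias_values(genome, iv, bias, "+")
  bm <- .bias_values(genome, iv, bias, "-")
  b <- bp + bm
  mask <- rep(FALSE, w)
  sel <- candidates$contig == iv$contig
  for (j in which(sel)) {
    lo <- max(candidates$start[j], iv$start) - iv$start + 1L
    hi <- min(candidates$end[j], iv$end) - iv$start
    if (lo <= hi) mask[lo:hi] <- TRUE
  }
  num <- .winsum(ifelse(mask, 0, obs), window_half)
  den <- .winsum(ifelse(mask, 0, b), window_half)
  bg <- ifelse(den > 0, num / den, 0) * b
  candidates$delta_hat <- NA_real_
  for (j in which(sel)) {
    lo <- max(candidates$start[j], iv$start) - iv$start + 1L
    hi <- min(candidates$end[j], iv$end) - iv$start
    if (lo > hi) next
    e <- sum(bg[lo:hi])
    candidates$delta_hat[j] <- if (e > 0) sum(obs[lo:hi]) / e else NA_real_
  }
  candidates
}

#' @export
print.expected_profile <- function(x, ...) {
  cat(sprintf("<expected_profile> %s:%d-%d  window_half=%d, mean expected %.3g/bp\n",
              x$interval$contig, x$interval$start, x$interval$end,
              x$window_half, mean(x$expected)))
  invisible(x)
}
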