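# fpkit — genomic DNase I footprinting toolkit

DNase I footprinting reads out transcription-factor occupancy at
nucleotide resolution: a protein bound to accessible chromatin shields
the phosphate backbone beneath it from nuclease attack, leaving a short
(~7–35 bp) interval of locally depleted cleavage inside a DNase
I-hypersensitive site (DHS). Detecting these footprints quantitatively
requires separating true protection from two confounders: the intrinsic
sequence preference of DNase I, and the technical variability of
cleavage counts. fpkit is an R toolkit for this analysis, aimed at
researchers working with DNase-seq (or similar nuclease accessibility)
data who want nucleotide-resolution occupancy calls with explicit error
control.

## What it computes

For each sample:

1. **Hexamer cleavage bias.** The relative cleavage preference of each
   6-mer context (3 bp 5′, the cleaved base, 2 bp 3′; minus-strand
   cleavages tallied against the reverse complement):
   pref(m) = (cleavages in context m / occurrences of m) ÷ (total
   cleavages / total contexts), normalized to mean 1.
2. **Expected cleavage rates.** Observed counts in a 101-bp window are
   redistributed in proportion to per-position preference:
   E[i] = W(obs) · b(i) / W(b), per strand, where W is the windowed sum.
3. **Negative-binomial dispersion model.** Counts binned by rounded
   expected rate; NB(μₙ, rₙ) fitted per bin by maximum likelihood; μ and
   log r smoothed by weighted regressions on the expected rate. This is
   the per-sample null for all testing.
4. **De novo footprint detection.** One-sided depletion p-values
   p = P(X ≤ obs) under NB(μ(E), r(E)); Stouffer combination over
   centred windows of width 3–13 bp (statistic = min over widths);
   empirical FDR from null counts resampled from the fitted model and
   pushed through the identical statistic pipeline; segmentation at
   FDR ≤ 1% with likelihood-refined boundaries.

Across samples:

5. **Empirical-Bayes posterior and consensus index.** Per-nucleotide
   posterior of protection combining a cross-sample occurrence prior
   (k+1)/(N+2) with occupied/unoccupied NB likelihoods; segments with
   posterior > 0.99 are collated across samples into consensus
   footprints (greedy max-support collation with median boundaries),
   and motif hits are assigned at ≥ 90% sequence overlap.
6. **Differential occupancy.** Per-nucleotide NB likelihood-ratio test
   of group depletion ratios φ_A vs φ_B (per-sample means/dispersions as
   offsets), χ²(1) p-values, BH correction, aggregation to footprints
   and DHSs.
7. **Allelic imbalance.** Allele-resolved cleavage tallies at
   heterozygous SNVs (≥ 35 informative reads), two-sided exact binomial
   test, BH q-values (imbalanced at q ≤ 0.2), and
   footprint-vs-non-footprint enrichment.

A synthetic-cohort simulator (`simulate_cohort()`) generates genomes,
DHSs, planted footprints with known depletion, group effects and
allele-specific variants — the ground truth used by the test suite.

## Worked example

Simulate a small cohort with planted truth, then run the full
per-sample pipeline:

```r
library(fpkit)

spec   <- cohort_spec(genome_length = 2e5, n_dhs = 50)
cohort <- simulate_cohort(spec, seed = 1)
truth  <- cohort$truth
sim    <- cohort$samples[[1]]

bias <- build_bias_table(truth$genome, sim$profiles)
#> <bias_model> k=6 offset=3, 4058/4096 k-mers observed, pref range [0.001, 4.22]

expected <- lapply(sim$profiles, expected_profile,
                   genome = truth$genome, bias = bias)
model <- fit_dispersion(sim$profiles, expected)
#> <dispersion_model> 39 bins over expected [19, 57]; mu = 0.693 + 0.984*e; r(mid) = 7.77

det <- detect_sample(sim$profiles, truth$genome, bias, model,
                     params = detect_params(seed = 1), sample_id = "sA01")
head(det$calls, 3)
#>   contig start   end width best_fdr sample
#> 1   chrS 12205 12229    24        0   sA01
#> 2   chrS 21291 21316    25        0   sA01
#> 3   chrS 22263 22279    16        0   sA01

evaluate_calls(det$calls, truth$footprints)[
  c("n_calls", "n_false", "fdp", "sensitivity", "width_spearman")]
#> $n_calls        23
#> $n_false        0
#> $fdp            0
#> $sensitivity    0.92
#> $width_spearman 0.974
```

The fitted dispersion model recovers the simulated conditions (the mean
trend is ~identity and r(mid) ≈ 7.8 against a generative r of 8); the
23 calls at the 1% empirical-FDR threshold contain no false positives,
recover 92% of the planted footprints at this depth, and their widths
rank-correlate with the planted widths at ρ = 0.97.

A thin command-line front end over the same functions is installed at
`inst/scripts/fpk.R` (`simulate` and `detect` subcommands).

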