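---
title: "Models and methods behind fpkit"
author: "fpkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fpkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpkit)
```

fpkit detects transcription-factor footprints — short intervals of
locally depleted DNase I cleavage inside hypersensitive sites (DHSs) —
and integrates them across samples. This vignette explains the models,
the tunable parameters and the numerical choices, in the order the
pipeline applies them.

## Coordinates and inputs

All coordinates are 0-based half-open (BED convention), everywhere.
Cleavage evidence enters either as aligned reads (BAM; each retained
read contributes one event at the 0-based position of its 5′-most
aligned base, per strand) or as precomputed per-base bedGraph tracks.
Reads flagged duplicate/secondary/unmapped/QC-fail are always excluded;
a mapping-quality threshold (`min_mapq`) and a minus-strand offset
(`minus_offset`, for enzymes with known end-chemistry shifts) are
exposed but default to 0 — plain 5′-end counting with no inter-strand
offset.

## Hexamer cleavage bias

DNase I cleaves with a reproducible sequence preference that must be
removed before protection can be read off the counts. The model is a
relative rate per k-mer context around the cleaved base (k = 6 with the
cleaved base at 0-based index 3, i.e. 3 bp 5′ and 2 bp 3′ on the
cleaved strand; both configurable). Minus-strand events are tallied
against the reverse-complement context, so one table serves both
strands. For context m,

$$\mathrm{pref}(m) = \frac{\text{cleavages in } m \,/\, \text{occurrences of } m}
                          {\text{total cleavages} \,/\, \text{total contexts}},$$

floored at `min_pref = 1e-3` (a context observed thousands of times
with zero cleavages should depress, not annihilate, the expected rate)
and rescaled so the mean preference over observed k-mers is exactly 1.
Contexts containing N, truncated by a contig end, or absent from
training behave as preference 1. Learning the table needs on the order
of \(4^k \times 10\) cleavages (a warning fires below that); it can be
learned from chromatin data directly or from a deproteinized-DNA
library through the same code path.

## Expected cleavage rates

The expected rate redistributes locally observed cleavage mass in
proportion to context preference. Per strand,

$$E_i = \frac{\sum_{j \in \mathrm{win}(i)} \mathrm{obs}_j}
             {\sum_{j \in \mathrm{win}(i)} b_j}\; b_i,$$

with a centred window of half-width `window_half = 50` (a 101-bp
window), truncated at the analyzed interval's ends. The window width
trades off locality against stability: 101 bp is long enough to
average over several footprints (so a single protected element only
mildly depresses its own background) and short enough to track
sub-DHS-scale changes in accessibility. When the window spans the whole
interval the expected profile conserves the observed total exactly;
expectation is computed per strand (bias is strand-specific) and summed
for testing (protection is not).

## Negative-binomial dispersion model

Observed counts given their expected rate are modelled negative
binomial, NB(μ(E), r(E)), fitted per sample: positions are binned by
round(E); within each bin with ≥ `min_positions_per_bin` (default 100)
positions, μ is the bin mean (the NB mean MLE) and r is a 1-D maximum
likelihood fit; at least 5 usable bins are required. The per-bin
estimates are then smoothed — a weighted least-squares line for μ vs E
with slope forced non-negative, and a weighted line of log r vs
log(1+E), down-weighting bins driven to the optimizer's Poisson ceiling
so a handful of saturated bins cannot dominate the slope. Outside the
fitted range both trends are clamped to their endpoint values; the
per-bin table is retained for audit. With deeply sequenced small
interval sets the integer bins become sparse; lower
`min_positions_per_bin` rather than widening the bins.

When the model is fitted on intervals that contain real footprints the
protected minority of positions inflates the apparent dispersion
slightly; this biases subsequent p-values conservative, which is the
safe direction for footprint calling.

The depletion test is one-sided and lower-tail, inclusive of the
observed value: p = P(X ≤ obs), deliberately conservative on discrete
counts (no mid-p correction). Positions with E < `min_expected = 0.1`
are untested, carry the sentinel p = 1 and can never seed a footprint.

## Detection: windowed statistic, empirical FDR, segmentation

Footprints span several nucleotides, so per-position p-values are
combined by Stouffer's method over centred windows:
\(Z_w(i) = \sum_{j} \Phi^{-1}(p_j) / \sqrt{w}\) for each odd width
w ∈ {3, 5, 7, 9, 11, 13}, and the per-position statistic is the minimum
over widths — short windows sharpen narrow footprints, long ones pick
up wide or weak protection. Untested positions (and p = 1) contribute
the capped null value z = +8.2; windows extending past the interval are
completed with the same cap.

Significance is assessed by an empirical FDR: counts are resampled from
the fitted NB model at each position's expected rate (`sample_null`),
pushed through the *identical* statistic pipeline, and

$$\widehat{\mathrm{FDR}}(t) = \frac{\#\{\text{null} \le t\}/R}
                                   {\max(1, \#\{\text{obs} \le t\})},$$

clipped to [0,1], evaluated at every observed statistic and monotonized
step-up (each position receives the minimum over thresholds at least as
large as its own), pooled across the analyzed interval set. R = 1 null
replicate suffices at genome scale where hundreds of thousands of null
positions are available; raise `n_null` for small interval sets.

Positions at FDR ≤ 1% form runs; runs separated by ≤ 3 bp are merged
and runs narrower than 6 bp discarded (genomic footprints are rarely
narrower than ~7 bp). Because the windowed statistic smears protection
by up to half a window, the segmented edges are then refined: within
± 4 bp (`refine_slack`) of each call's edges, the boundary pair
maximizing a two-level NB likelihood (counts inside at δ̂·μ with δ̂
estimated from the call, flanks at μ) is kept. Refinement sharpens
reported widths substantially — on the benchmark simulations the rank
correlation between planted and called widths rises from ≈ 0.89 to
≈ 0.98 — and never changes which elements are called.

For measuring the depth of a candidate footprint, `estimate_depletion`
computes the background expectation with all candidate positions masked
out of the smoothing window; without masking, a wide weak footprint
depresses its own background and the estimate is biased upward by up to
~0.08 at δ = 0.4, w = 30.

## Empirical-Bayes posterior and consensus index

Per-sample, per-nucleotide:

$$P(\text{occ} \mid \text{data}) =
  \frac{\pi \, L_{\mathrm{occ}}}{\pi \, L_{\mathrm{occ}} + (1-\pi)\, L_{\mathrm{unocc}}},$$

with prior \(\pi_i = (k_i + 1)/(N + 2)\) from the number of samples
whose de novo calls cover position i (Laplace pseudocounts keep the
prior inside (0,1), so an element unseen in the cohort can still be
recovered by one deep sample). The unoccupied likelihood is the NB pmf
at the fitted mean; the occupied likelihood is a uniform mixture over
depletion ratios δ ∈ {0.05, …, 0.75} applied to the mean. Because a
bound factor occludes a run of adjacent phosphates, the likelihoods are
evaluated over a 3-bp centred evidence window with a single δ shared
across the window (`evidence_half = 1`; 0 recovers the exact
per-position update). Without this, the posterior hovers around the
0.99 threshold inside true footprints at moderate depth and segments
fragment. Untested positions contribute no likelihood factors and
inherit the prior.

Segments with posterior > 0.99 are collated across samples: repeatedly
take the genomic position covered by the most remaining segments (ties:
leftmost), gather all segments covering it, emit
[lower-median start, upper-median end) with support = distinct
contributing samples, and remove the gathered segments. The procedure
is independent of input order, never merges abutting consensus
footprints, and snapping overlapping segments to shared median
boundaries is what makes the consensus index markedly more reproducible
between replicates than the replicates' independent de novo calls.
Motif hits (precomputed; scanning is out of scope) are assigned to a
consensus footprint when the overlap covers ≥ 90% of the motif length,
ranked by match score.

## Differential occupancy

For two groups of samples within accessibility-matched DHSs (kept when
≥ 10 samples per group have normalized cleavage density ≥ 1), each
tested position is modelled as obs_s ~ NB(φ_{g(s)}·μ_s, r_s) with μ_s,
r_s from each sample's own dispersion model — the per-sample expected
rates act as offsets, so φ is a group-level relative cleavage ratio.
φ is optimized on the log scale over [10⁻³, 10] by 1-D search
(tolerance 10⁻⁶, endpoints checked); the likelihood-ratio statistic
2(ℓ_free − ℓ_shared) is referred to χ²(1), and BH correction is pooled
across all tested positions in the run (a per-DHS option would condition
on much smaller families; pooled is the default and the documented
choice). A footprint is differential iff it contains a position with
q ≤ 0.05; a DHS iff it contains a differential footprint.

## Allelic imbalance

At heterozygous SNVs, reads from het-genotyped samples are tallied by
the base they carry (base quality ≥ 20); variants with fewer than 35
informative (ref+alt) reads are untestable — the threshold applies
after discarding third-allele bases. The test is the two-sided exact
binomial p obtained by doubling the smaller tail and capping at 1:
simple, conservative on discrete counts, with BH q-values and an
imbalance flag at q ≤ 0.2. No reference-mapping-bias correction is
applied; `expected_ratio` is exposed so a measured bias can be supplied.
Enrichment of imbalanced variants inside footprints is summarised as
the ratio of imbalanced fractions in footprinted vs non-footprinted DHS
positions with a Fisher exact p; empty partitions yield NA sentinels.

## The synthetic cohort

`cohort_spec()` defaults describe the benchmark conditions used by the
test suite and the acceptance script: a 2 Mb uniform-ACGT genome; 500
non-overlapping 200-bp DHSs (≥ 500 bp apart) with per-DHS rate
multipliers uniform on [1, 2]; footprints of width 8–30 bp and
depletion δ uniform on [0.1, 0.4] planted in half of the DHSs (one per
DHS, ≥ 10 bp from the DHS edge); a hexamer preference table drawn
log-normal(0, 0.25) and normalized; per-sample depths uniform on
[20, 40] expected cleavages/bp; NB noise with size r = 8. Each strand
draws NB(λ/2, r/2) — the strands share the success probability, so the
combined per-nucleotide count is exactly NB(λ, r) and the planted r is
stated (and recovered by the dispersion module) on the combined scale.
Group-specific footprints apply δ only in the matching group's samples.
Variant-linked footprints modulate the protected rate per allele
(default: the alt allele halves protected-region cleavage); the total
count at the variant site carries the NB technical variability while
each cleavage's allele of origin is a Bernoulli draw proportional to
the allele rates, which is how read sampling behaves. The simulator
shares no code with the fitting path.

What the simulator does *not* emulate: mappability structure, fragment
length and PCR artefacts, chromatin-scale covariance between
neighbouring positions, nucleosome signal, reference-mapping bias at
variants, or realistic DHS shape (plateau rather than peaked). Passing
tests therefore demonstrate the statistical machinery under its own
generative assumptions, not performance on any real library.

## Problem sizes and numerical choices

The suite exercises the full pipeline on three simulated 2 Mb cohorts
(~250 planted footprints each; about half a minute per cohort on one
CPU), plus targeted simulations: null calibration at 10⁵ positions
(DKW envelope at α = 10⁻³), differential-test uniformity at 10⁴
positions pooled over three seeds, and dispersion recovery at
10⁵ positions per r ∈ {2, 8, 32}. Key numerical guards: p-values are
floored at the smallest positive double before Φ⁻¹; z-values are capped
at +8.2; NB sizes are clamped to [10⁻³, 10⁸]; the likelihood window
uses log-space sums; φ and boundary searches check interval endpoints.
Ties in the consensus collation are broken by coordinate, never by
input order.

## Known limitations

- The expected-rate window is fixed-width; DHS-adaptive windows are not
  implemented.
- The dispersion model carries no positional covariates (GC,
  mappability) beyond the hexamer bias.
- The differential test supports exactly two groups, without covariates.
- Allelic analysis pools counts across samples and individuals; no
  beta-binomial overdispersion model and no haplotype phasing.
- Paired-end fragment modelling and CRAM input are out of scope; the
  only hook for transposase-style end chemistry is `minus_offset`.
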