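---
title: "Methods: copy-number BRCA1-like classification and treatment-benefit analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number BRCA1-like classification and treatment-benefit analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brcalike)
```

`brcalike` assembles the analytic chain of a predictive-biomarker study in
early-stage triple-negative breast cancer: shallow whole-genome copy-number
profiling, BRCA1-like classification by a nearest shrunken centroid model,
cross-platform score concordance, and Cox treatment-by-marker interaction
analysis. This vignette explains each model, its assumptions, the tunable
parameters, and the design decisions taken where the methodology left real
choices open.

## Copy-number profiling

Reads (or precomputed counts) are placed on a grid of 20 kb bins tiling
autosomes 1–22, with 0-based half-open coordinates (the BED convention; a
read belongs to the bin containing its 5' start). The pipeline is

count → filter → GC-correct → reference slope → log2 ratio

* **Filtering.** A bin is analysable iff it is not blacklisted and its
  reference mappability — the fraction of 65 bp subsequences that align
  uniquely back to their origin — is at least 0.2. The threshold is
  inclusive: only mappability *below* 0.2 is excluded, so 0.2 exactly is
  kept. Blacklisted bins still receive simulated counts; removing them is
  deliberately the pipeline's job so tests can exercise the filter.
* **GC correction.** Read yield depends smoothly and multiplicatively on
  bin GC fraction. A loess curve (degree 2, tricube weights, span 0.3 by
  default) of log-count against GC is fitted on analysable bins with
  mappability strictly above 0.8 — the bins whose depth responds most
  cleanly to GC — and every analysable bin's count is divided by the
  fitted level at its GC and rescaled by the fit's mean level, preserving
  overall scale. Two numerical choices matter here. The fit is on the
  *log* scale because the bias is multiplicative; a purely exponential GC
  effect is then removed exactly. And the loss is *robust*
  (`family = "symmetric"`): focal copy-number aberrations are genuine
  biology, not GC bias, and a squared-error fit lets a large deletion drag
  the local GC curve toward itself, attenuating the very signal the
  profile should show. Bins with GC outside the fitted range reuse the
  nearest fitted value; zero-count bins are left out of the fit but still
  corrected.
* **Reference slope.** Expected depth is proportional to mappability.
  Analysable bins are grouped into 20 equal-width mappability intervals on
  [0.2, 1]; each non-empty interval contributes its centre (median
  mappability, median corrected count), weighted by occupancy, and a
  weighted least-squares line through the origin over these centres gives
  the slope that converts mappability into an expected reference count.
  The grouping realizes "the centre of GC-corrected counts per mappability
  density" as density-weighted group centres — one defensible reading of a
  terse prescription; medians make the centres insensitive to aberrant
  bins.
* **Log2 ratio.** For each analysable bin,
  `log2(corrected / (slope * mappability))`. Bins whose corrected count is
  non-positive are dropped from the inclusion mask rather than patched
  with a pseudo-count, which would fabricate signal in low-count bins.

Two structural guarantees follow from linearity and are enforced by tests:
multiplying all counts by any constant leaves the profile unchanged (depth
invariance), and on GC-biased flat-copy simulations the profile is flat and
uncorrelated with GC.

## BRCA1-like classification

The classifier is a two-class nearest shrunken centroid model. With class
sizes *n<sub>j</sub>*, pooled within-class standard deviations
*s<sub>k</sub>*, fudge constant *s₀* (the median of the *s<sub>k</sub>*,
guarding near-zero denominators) and
*m<sub>j</sub>* = √(1/n<sub>j</sub> − 1/n), the per-feature contrasts

d<sub>jk</sub> = (x̄<sub>jk</sub> − x̄<sub>k</sub>) / (m<sub>j</sub> (s<sub>k</sub> + s₀))

are soft-thresholded by Δ, and centroids reconstructed as
x̄'<sub>jk</sub> = x̄<sub>k</sub> + m<sub>j</sub>(s<sub>k</sub> + s₀) d'<sub>jk</sub>.
Scoring computes δ<sub>j</sub>(x) = Σ<sub>k</sub> (x<sub>k</sub> −
x̄'<sub>jk</sub>)² / (s<sub>k</sub> + s₀)² − 2 log π<sub>j</sub> and the
BRCA1-like posterior exp(−δ<sub>B</sub>/2) / Σ<sub>j</sub> exp(−δ<sub>j</sub>/2),
evaluated as a numerically stable softmax. Δ is chosen from a grid by
stratified cross-validated accuracy (5 folds by default); ties resolve to
the **largest** tied Δ, the most parsimonious model among equals.

Decisions worth stating explicitly:

* The published model's centroids are not public. The package therefore
  ships the *trainer* plus a JSON model format, and every test runs on
  synthetically trained models: the mechanism is faithful; the parameters
  are not claimed to be the published ones.
* The decision threshold defaults to 0.63 on the BRCA1-like posterior, and
  a score exactly at the threshold is called BRCA1-like (the cutoff is
  "at or above").
* Class priors default to equal and are configurable; nothing in the
  method fixes them.
* Profiles are mapped onto a model's feature grid by averaging the
  included bins overlapping each feature interval. Features with no
  included bins are imputed with the overall centroid — the score-neutral
  direction — and a profile missing more than half its features is
  rejected as too low-quality to classify, mirroring quality exclusions in
  practice. How the original aCGH-era classifier mapped sequencing bins
  onto its clone-based feature space is not public; the feature-grid
  abstraction here is a general mechanism, not a claim about that mapping.

## Score concordance

Given pairs of a cutoff-bearing score *a* (in [0, 1]) and an arbitrary-scale
score *b*, the percentile of the cutoff in *a* is computed by strict
"below" counting (100·#{a < cutoff}/n), *b* is cut at its own empirical
quantile (linear interpolation, type 7) at that percentile, with ties going
to the high label, and agreement is tabulated. These conventions make
marginal matching — the fraction labeled low in *b* equals that in *a* —
exact to within 1/n on tie-free data, which is the construction's purpose.
Nearest-rank instead of interpolated quantiles could move single samples
across the cut; discrepancies of one sample in the 2×2 table are within
the method's resolution.

## Survival analysis

RFS is time from randomization to recurrence or death from any cause,
whichever comes first; OS is time to death from any cause; both are
censored at last follow-up. Median follow-up uses the reverse
Kaplan–Meier estimator (indicators flipped; the median is the first time
the curve reaches 0.5, or "not reached"). Cox models are fitted by
`survival::coxph` behind a thin wrapper that fixes the reporting layout
(coefficients, HRs, 95% Wald CIs, p-values, log partial likelihood) and
raises on non-convergence or near-separation. Efron's ties correction is
the default — times in years make ties plausible — with Breslow available
because closed-form partial-likelihood oracles and some legacy software
use it. Proportional hazards are checked by correlating scaled Schoenfeld
residuals with event time (identity transform).

The treatment-by-marker interaction model deserves its own note. It is
parameterized as treatment + treatment×marker with a **marker-stratified
baseline hazard**, rather than a marker main-effect coefficient on a
shared baseline. With the stratified baseline the within-stratum treatment
hazard ratios from the full model coincide exactly with marker-subset Cox
fits — the way per-stratum HRs are usually presented — whereas with a
shared baseline they differ slightly (the strata share risk sets). The
interaction coefficient is then the log-ratio of the stratum HRs and its
Wald test is the reported interaction p-value. The marker's own prognostic
HR, which the stratified model absorbs, comes from a separate marker-only
model. Adjustment is one covariate at a time, never all at once —
appropriate when events are few — and `adjust_one_at_a_time()` reports the
range of adjusted interaction p-values. Categorical covariates are
dummy-coded against their first configured level.

## Synthetic data: what it emulates, and what it does not

The generators produce every input with known ground truth, under a single
integer seed each (no global RNG state is left disturbed).

* **Bin grids**: GC as a moving average (window 25 bins) of uniform noise
  rescaled to [0.3, 0.7] — spatially autocorrelated like real GC without
  external tracks; mappability with configurable tails below 0.2 (default
  2%) and above 0.8 (default 85%); blacklist flags on 1% of bins.
* **Copy-number signal**: additive region shifts, random segment shifts
  (breakpoints Poisson at `segment_rate` per 100 Mb), Gaussian bin noise.
* **Counts**: Poisson with mean
  `depth · 2^log2 · mappability · exp(b0 + b1·gc + b2·gc²)`; Poisson by
  default so calibration oracles are closed-form, with an optional
  negative-binomial overdispersion parameter. The default depth used in
  examples, 100 reads per 20 kb bin, corresponds to roughly 0.3× coverage
  with 65 bp reads — shallow-sequencing territory.
* **Cohorts**: exponential event times with hazard
  `baseline · hr_marker^(marker⁺) · stratum treatment HR`, administrative
  censoring, defaults baseline 0.05/year and 12-year censoring (event
  fractions like a long-follow-up adjuvant trial), stratum treatment HRs
  defaulting to 0.23 and 0.66, and clinicopathologic covariates drawn from
  frequencies typical of an early-stage TNBC trial population. Each
  patient has one latent event time, recorded as an upfront death with
  probability 0.25 and otherwise as a recurrence with a possible later
  death; this keeps the configured hazard exactly equal to the RFS hazard
  (so closed-form recovery oracles apply) while giving OS its own times.
* **Paired scores**: a Gaussian copula on ranks; the copula correlation is
  solved by `uniroot` against the exact theoretical concordant fraction,
  computed by one-dimensional integration of the bivariate-normal orthant
  probability. Score *a* is uniform (a calibrated probability); score *b*
  is log-normal around 6 — an arbitrary positive scale.

What the synthetic data does **not** emulate: real aberration landscapes
(which genomic regions characterize BRCA1-like tumours is treated as a free
parameter, not a biological claim), FFPE artefacts, replication-timing or
fragment-length biases, non-exponential hazards, informative censoring, or
correlated covariates. Passing tests therefore demonstrate that the
*machinery* is correct and calibrated under its stated model — not that
the biological classification itself is valid on real tumours.

## Simulation designs behind the headline checks

The problem sizes in `scripts/acceptance.R` and the acceptance tests are
chosen so each check's Monte-Carlo error is small against its tolerance:

* Null flatness: 5000 bins (four 25 Mb chromosomes), depth 100, quadratic
  GC bias `exp(-2.25·(gc-0.5)²)`; the included-bin median log2 and its GC
  correlation are both near zero well inside the |median| < 0.02 and
  |cor| < 0.05 bounds.
* Region recovery: a 50-bin single-copy loss planted in a
  GC-representative window (mean GC closest to the genome median) and read
  back at depth 600 (~2× coverage), where the region median's MC standard
  deviation is ≈ 0.016 against the ±0.05 check. At depth 100 the check
  would be a coin flip for a correct pipeline, and planting the region at
  a GC extreme confounds recovery with the sparse tail of the GC fit — a
  real, documented limitation of GC correction, not a test target.
* Stratum-HR recovery: 2000 patients per arm×marker cell with an
  event-rich design (baseline 0.2/year, 15-year censoring), giving the
  BRCA1-like-stratum HR an MC standard deviation ≈ 0.019 against ±0.05;
  estimator unbiasedness was verified over 40 replicates. Null
  calibration uses 200 replicates of 250 patients per cell: interaction
  p-values are checked for uniformity (Kolmogorov–Smirnov) and the
  stratum-HR Wald CI for 93–97% coverage.
* Classifier checks: oracle equivalence on 200 random vectors against a
  brute-force nearest-centroid rule; feature recovery on 80 samples × 200
  features with 30 planted features (shift 1.0, sd 0.3), where surviving
  features at the CV-chosen Δ are compared to the planted set.

## Known limitations

* Focal aberrations at extreme GC (where the GC fit has little data) are
  attenuated; robust loss mitigates but cannot eliminate this.
* The reference-slope reading of "centre of counts per mappability
  density" is one defensible interpretation; alternatives (means instead
  of medians, different interval counts) would shift profiles by small
  constants.
* The Wald interaction test is anti-conservative in very small cells; the
  null-calibration check runs at 250 patients per cell, not at
  trial-subgroup sizes.
* The classifier assumes feature-wise (diagonal) covariance, as the
  shrunken-centroid family does; correlated features are handled only
  through cross-validated shrinkage.
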