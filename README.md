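# brcalike

Homologous recombination deficiency (HRD) marks breast tumours that cannot
repair DNA double-strand breaks error-free, and it is a candidate predictive
biomarker for DNA-damaging and antimetabolite chemotherapy in early-stage
triple-negative breast cancer (TNBC). One established HRD readout is the
*BRCA1-like* copy-number profile: a genome-wide aberration pattern
resembling germline *BRCA1*-mutated tumours, callable from shallow
whole-genome sequencing. `brcalike` implements the full analytic chain of a
predictive-biomarker study around this readout, for biostatisticians and
translational researchers who want each stage as a tested, reusable
component:

1. **Copy-number profiling** — reads counted on a 20 kb autosomal bin grid;
   bins removed when blacklisted or with mappability < 0.2; local GC effects
   corrected with a robust loess fitted on well-mappable (mappability > 0.8)
   bins; a line through the origin of GC-corrected counts per mappability
   density scales mappability to reference counts; profiles are the per-bin
   log2 ratios of GC-corrected counts over these scaled reference counts.
2. **BRCA1-like classification** — a nearest shrunken centroid classifier.
   Per feature *k* and class *j*, the standardized contrast
   *d*<sub>jk</sub> = (x̄<sub>jk</sub> − x̄<sub>k</sub>) / (m<sub>j</sub>(s<sub>k</sub> + s₀))
   is soft-thresholded, |d| ↦ max(|d| − Δ, 0), and class posteriors follow
   from the standardized distances to the shrunken centroids. A profile with
   a BRCA1-like posterior ≥ 0.63 is called BRCA1-like.
3. **Cross-platform concordance** — a second continuous score without an
   established cutoff (e.g. an RNA-based BRCAness signature) is dichotomized
   at the percentile at which the 0.63 cutoff falls in the classifier-score
   distribution, then agreement is tabulated 2×2.
4. **Survival analysis** — recurrence-free (RFS) and overall survival (OS)
   endpoints, Kaplan–Meier curves with risk tables, reverse-Kaplan–Meier
   median follow-up, and Cox proportional-hazards models with a
   treatment×marker interaction (within-stratum treatment hazard ratios,
   Wald interaction test, one-covariate-at-a-time adjustment, Schoenfeld
   proportional-hazards checks).
5. **Synthetic data** — generators for every input above (annotated bin
   grids, class-specific copy-number signals, Poisson read counts with
   multiplicative GC bias, paired biomarker scores with a tunable
   concordance, randomized two-arm cohorts with marker-dependent treatment
   hazard ratios), all with known ground truth.

## Worked example

Train a classifier on synthetic two-class profiles, then analyse a
simulated randomized cohort whose marker-dependent treatment effects are
known:

```r
library(brcalike)

set.seed(20)
x <- matrix(rnorm(80 * 200, 0, 0.3), 80, 200)   # 200 genomic features
x[41:80, 1:30] <- x[41:80, 1:30] + 1            # 30 discriminative features
model <- nsc_train(x, rep(c("non-BRCA1-like", "BRCA1-like"), each = 40),
                   seed = 21)
model
#> Shrunken centroid classifier
#>   features: 200 ( 17 with non-zero contrast )
#>   delta: 7.73  s0: 0.2966
#>   threshold: 0.63 ( >= threshold => BRCA1-like )
#>   training n: non-BRCA1-like 40, BRCA1-like 40

co <- simulate_cohort(survival_sim_config(n_per_cell = 500, seed = 22))
interaction_analysis(co, endpoint = "rfs")
#> Treatment-by-marker interaction, RFS (efron ties)
#> non-BRCA1-like tumours
#>   T+CEF    212/500  (reference)
#>   TX+CEX   73/500  HR 0.28 (95% CI 0.22-0.37)
#> BRCA1-like tumours
#>   T+CEF    235/500  (reference)
#>   TX+CEX   163/500  HR 0.63 (95% CI 0.51-0.76)
#> P-interaction = 0.00
```

The cross-validated shrinkage Δ = 7.73 keeps 17 of 200 features (a subset
of the 30 planted ones). The cohort was simulated with true within-stratum
treatment hazard ratios 0.23 (non-BRCA1-like) and 0.66 (BRCA1-like); at 500
patients per cell the model recovers 0.28 and 0.63, and the interaction is
detected. Paired biomarker scores behave the same way:

```r
pairs <- simulate_paired_scores(103, target_concordance = 0.786, seed = 23)
score_concordance(pairs, cutoff_a = 0.63)
#> Concordance: 74.8% (77/103)
#> cutoff percentile 59.2; score_b cutoff 6.91
#>       b
#> a      low high
#>   low   48   13
#>   high  13   29
```

At n = 103 the realized concordant fraction (74.8%) scatters around the
78.6% target; it converges to the target as n grows.

A thin command-line front end (`simulate`, `profile`, `train`, `predict`,
`concord`, `survival`) is provided via `run_cli()` and
`inst/cli/brcalike.R`; every output directory carries a provenance JSON
naming the command, configuration and seed.

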