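# Synthetic-data generators: bin grids, copy-number signals, biased counts,
# cohorts and paired scores, each checked against closed-form expectations.

test_that("bin grids tile chromosomes with half-open intervals", {
  g <- sim_genome(c(chr1 = 1e5))
  bins <- make_bin_grid(g, seed = 1)
  expect_equal(nrow(bins), 5)
  expect_equal(bins$end[5], 1e5)
  expect_equal(bins$start, seq(0, 8e4, 2e4))

  g2 <- sim_genome(c(`1` = 6e4))
  bins2 <- make_bin_grid(g2, seed = 1)
  expect_equal(bins2$start, c(0, 2e4, 4e4))
  expect_equal(bins2$end[3], 6e4)

  # tiling completeness across a multi-chromosome genome
  g3 <- sim_genome(c(chr1 = 1.23e6, chr2 = 7.7e5, chr10 = 9.99e5))
  bins3 <- make_bin_grid(g3, seed = 2)
  expect_equal(sum(bins3$end - bins3$start), sum(g3$chrom_lengths))
})

test_that("bin grids are deterministic given a seed and reject non-autosomes", {
  g <- sim_genome(c(`3` = 5e5, `17` = 5e5))
  expect_identical(make_bin_grid(g, seed = 42), make_bin_grid(g, seed = 42))
  expect_error(sim_genome(c(chrX = 1e6)), "chrX")
  expect_error(sim_genome(c(`1` = 1e6, MT = 1e5)), "MT")
})

test_that("bin annotation tracks stay within their documented ranges", {
  bins <- make_bin_grid(standard_genome(2, 10), seed = 5,
                        frac_low_mapp = 0.1, frac_high_mapp = 0.6,
                        frac_blacklist = 0.05)
  expect_true(all(bins$gc >= 0.3 & bins$gc <= 0.7))
  expect_true(all(bins$mappability >= 0 & bins$mappability <= 1))
  # configured tail fractions are realized up to binomial noise
  expect_equal(mean(bins$mappability < 0.2), 0.1, tolerance = 0.35)
  expect_equal(mean(bins$mappability > 0.8), 0.6, tolerance = 0.1)
  expect_gt(mean(bins$blacklisted), 0)
})

test_that("simulated signal is additive over regions, segments and noise", {
  bins <- flat_bins(50)
  null_spec <- cnv_class_spec("non-BRCA1-like", noise_sd = 0,
                              segment_rate = 0)
  expect_equal(simulate_profile(bins, null_spec, seed = 1)$log2, rep(0, 50))

  regions <- data.frame(chrom = "1", start = 9 * 2e4, end = 20 * 2e4,
                        shift = -1.0)
  spec <- cnv_class_spec("BRCA1-like", aberration_regions = regions,
                         noise_sd = 0, segment_rate = 0)
  sig <- simulate_profile(bins, spec, seed = 1)$log2
  expect_equal(sig[10:20], rep(-1, 11))
  expect_equal(sig[-(10:20)], rep(0, 39))

  off_grid <- data.frame(chrom = "2", start = 0, end = 1e5, shift = 1)
  spec2 <- cnv_class_spec("BRCA1-like", aberration_regions = off_grid,
                          noise_sd = 0)
  expect_warning(out <- simulate_profile(bins, spec2, seed = 1), "ignored")
  expect_equal(out$log2, rep(0, 50))
})

test_that("per-bin noise sd matches the stated Gaussian model", {
  bins <- flat_bins(50)
  spec <- cnv_class_spec("BRCA1-like", noise_sd = 0.1, segment_rate = 0)
  reps <- sapply(1:1000, function(i)
    simulate_profile(bins, spec, seed = 1000 + i)$log2)
  per_bin_sd <- apply(reps, 1, sd)
  expect_true(all(abs(per_bin_sd - 0.1) < 0.01))
})

test_that("count model mean follows depth, mappability and GC bias", {
  bins <- flat_bins(10000, gc = runif(10000, 0.3, 0.7))
  counts <- simulate_counts(bins, numeric(10000), mean_depth = 100,
                            seed = 3)
  expect_lt(abs(mean(counts) / 100 - 1), 0.01)

  counts2 <- simulate_counts(bins, numeric(10000), mean_depth = 200,
                             seed = 3)
  expect_lt(abs(mean(counts2) / mean(counts) - 2), 0.02 * 2)

  # Poisson calibration: variance/mean ratio near 1 at flat copy number
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.05)

  expect_error(simulate_counts(bins, numeric(10000), mean_depth = 0),
               "mean_depth")
  expect_error(simulate_counts(bins, numeric(10000), mean_depth = -5),
               "mean_depth")
})

test_that("copy-number and mappability scale expected counts multiplicatively", {
  bins <- flat_bins(8000, mappability = 0.5)
  counts <- simulate_counts(bins, rep(1, 8000), mean_depth = 100, seed = 9)
  # 2^1 * 0.5 cancels back to the nominal depth
  expect_lt(abs(mean(counts) / 100 - 1), 0.02)
  over <- simulate_counts(bins, numeric(8000), mean_depth = 100,
                          overdispersion = 0.1, seed = 9)
  expect_gt(var(over) / mean(over), 1.5)
})

test_that("null cohorts have exchangeable cells and exponential event fractions", {
  cfg <- survival_sim_config(n_per_cell = 2000, baseline_hazard = 0.1,
                             hr_treatment_in_marker_neg = 1,
                             hr_treatment_in_marker_pos = 1, hr_marker = 1,
                             admin_censor_time = 10, seed = 21)
  co <- simulate_cohort(cfg)
  ep <- derive_endpoints(co)
  events <- tapply(ep$rfs_event, list(co$arm, co$marker), sum)
  n_cell <- tapply(ep$rfs_event, list(co$arm, co$marker), length)
  hom <- suppressWarnings(
    stats::chisq.test(rbind(as.vector(events),
                            as.vector(n_cell - events))))
  expect_gt(hom$p.value, 0.001)
  # closed-form exponential CDF: 1 - exp(-0.1 * 10)
  expect_equal(mean(ep$rfs_event), 1 - exp(-1), tolerance = 0.02)
})

test_that("exponential MLE on a null cohort recovers the baseline hazard", {
  cfg <- survival_sim_config(n_per_cell = 1000, baseline_hazard = 0.08,
                             hr_treatment_in_marker_neg = 1,
                             hr_treatment_in_marker_pos = 1, hr_marker = 1,
                             admin_censor_time = 10, seed = 22)
  ep <- derive_endpoints(simulate_cohort(cfg))
  lambda_hat <- sum(ep$rfs_event) / sum(ep$rfs_time)
  expect_lt(abs(lambda_hat / 0.08 - 1), 0.05)
})

test_that("cohort simulation is deterministic and internally consistent", {
  cfg <- survival_sim_config(n_per_cell = 100, seed = 5)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1, co2)
  expect_true(all(co1$followup_time > 0))
  expect_true(all(is.na(co1$time_to_recurrence) |
                  co1$time_to_recurrence <= co1$followup_time))
  expect_true(all(is.na(co1$time_to_death) |
                  co1$time_to_death <= co1$followup_time))
  expect_true(all(table(co1$arm, co1$marker) == 100))
})

test_that("paired scores hit the target concordance", {
  ps1 <- simulate_paired_scores(500, 1.0, seed = 1)
  expect_identical(rank(ps1$score_a), rank(ps1$score_b))
  expect_equal(score_concordance(ps1)$concordant_fraction, 1.0)

  ps <- simulate_paired_scores(1e5, 0.786, seed = 2)
  expect_equal(score_concordance(ps)$concordant_fraction, 0.786,
               tolerance = 0.01 / 0.786)

  ps5 <- simulate_paired_scores(1e5, 0.5, seed = 3)
  expect_equal(score_concordance(ps5)$concordant_fraction, 0.5,
               tolerance = 0.01 / 0.5)

  expect_error(simulate_paired_scores(1e3, 1.2), "target_concordance")
  expect_error(simulate_paired_scores(5, 0.8), "at least 10")
})
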