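# Nearest shrunken centroid classifier: grid mapping, training, shrinkage,
# posterior scoring and cohort summaries.

toy_profile <- function(ratios, included = TRUE, bin_size = 2e4) {
  n <- length(ratios)
  starts <- (seq_len(n) - 1) * bin_size
  out <- data.frame(chrom = "1", start = starts, end = starts + bin_size,
                    log2_ratio = ratios,
                    included = rep_len(included, n))
  class(out) <- c("genomic_profile", "data.frame")
  out
}

test_that("profiles map onto feature grids by overlap-mean", {
  prof <- toy_profile(c(0.2, 0.4, -0.5, 0.1))
  grid_identity <- data.frame(chrom = "1", start = (0:3) * 2e4,
                              end = (1:4) * 2e4)
  expect_equal(map_to_feature_grid(prof, grid_identity),
               c(0.2, 0.4, -0.5, 0.1), ignore_attr = TRUE)

  grid_span <- data.frame(chrom = "1", start = 0, end = 4e4)
  expect_equal(as.numeric(map_to_feature_grid(prof, grid_span)), 0.3)
})

test_that("low-quality profiles (mostly missing features) are rejected", {
  prof <- toy_profile(rep(0.1, 10),
                      included = c(rep(TRUE, 4), rep(FALSE, 6)))
  grid <- data.frame(chrom = "1", start = (0:9) * 2e4, end = (1:10) * 2e4)
  expect_error(map_to_feature_grid(prof, grid), "quality")
  v <- map_to_feature_grid(prof, grid, max_missing = 0.8)
  expect_equal(sum(attr(v, "missing")), 6)
})

test_that("delta = 0 reproduces unshrunken class means", {
  set.seed(51)
  dat <- make_class_data(n_per_class = 10, p = 20, planted = 1:5)
  m <- nsc_train(dat$x, dat$y, delta_grid = 0)
  for (cl in c("non-BRCA1-like", "BRCA1-like"))
    expect_equal(unname(m$class_centroids[cl, ]),
                 unname(colMeans(dat$x[dat$y == cl, ])), tolerance = 1e-12)
})

test_that("full shrinkage collapses centroids and scores to the prior", {
  set.seed(52)
  dat <- make_class_data(n_per_class = 10, p = 20, planted = 1:5)
  m <- nsc_train(dat$x, dat$y, delta_grid = 1e6)
  expect_equal(unname(m$class_centroids[1, ]), unname(m$overall_centroid))
  expect_equal(unname(m$class_centroids[2, ]), unname(m$overall_centroid))
  expect_equal(nsc_score(m, dat$x[1, ])$score, 0.5, tolerance = 1e-12)
})

test_that("training rejects degenerate label sets", {
  set.seed(53)
  x <- matrix(rnorm(200), 20, 10)
  expect_error(nsc_train(x, rep("BRCA1-like", 20)), "both classes")
  expect_error(nsc_train(x, c(rep("BRCA1-like", 17),
                              rep("non-BRCA1-like", 3))), "at least 5")
})

test_that("well-separated classes cross-validate accurately and recover planted features", {
  set.seed(54)
  dat <- make_class_data(n_per_class = 40, p = 200, planted = 1:30,
                         shift = 1.0, sd = 0.3)
  m <- nsc_train(dat$x, dat$y, seed = 55)
  expect_gte(max(m$cv$accuracy), 0.95)
  surv <- surviving_features(m)
  expect_gte(mean(surv %in% dat$planted), 0.8)
})

test_that("posterior scores match a brute-force discriminant oracle", {
  set.seed(56)
  dat <- make_class_data(n_per_class = 8, p = 3, planted = 1:2, shift = 1)
  m <- nsc_train(dat$x, dat$y, delta_grid = 0)
  for (i in c(1, 5, 9, 16)) {
    v <- dat$x[i, ]
    d <- sapply(1:2, function(j)
      sum((v - m$class_centroids[j, ])^2 / (m$pooled_sd + m$s0)^2) -
        2 * log(m$priors[j]))
    oracle <- exp(-d[2] / 2) / sum(exp(-d / 2))  # class 2 = BRCA1-like
    expect_equal(nsc_score(m, v)$score, unname(oracle), tolerance = 1e-12)
  }
})

test_that("posteriors sum to one and a score at the threshold is BRCA1-like", {
  set.seed(57)
  dat <- make_class_data(n_per_class = 10, p = 10, planted = 1:3)
  m <- nsc_train(dat$x, dat$y, delta_grid = 0)
  r <- nsc_score(m, dat$x[3, ])
  expect_equal(sum(r$posterior), 1, tolerance = 1e-9)
  expect_true(r$score >= 0 && r$score <= 1)

  # the >= convention: a score exactly at the threshold is called positive.
  # a fully shrunk equal-prior model scores exactly 0.5; set the threshold
  # there to realize an exact tie.
  m2 <- nsc_train(dat$x, dat$y, delta_grid = 1e6, threshold = 0.5)
  r2 <- nsc_score(m2, dat$x[3, ])
  expect_identical(r2$score, 0.5)
  expect_identical(r2$label, "BRCA1-like")
  # default threshold is the established 0.63
  expect_equal(m$threshold, 0.63)
})

test_that("scores increase monotonically toward the BRCA1-like centroid", {
  set.seed(58)
  dat <- make_class_data(n_per_class = 15, p = 25, planted = 1:8)
  m <- nsc_train(dat$x, dat$y, delta_grid = 0)
  from <- m$class_centroids["non-BRCA1-like", ]
  to <- m$class_centroids["BRCA1-like", ]
  scores <- sapply(seq(0, 1, 0.05), function(t)
    nsc_score(m, from + t * (to - from))$score)
  expect_true(all(diff(scores) >= -1e-12))
})

test_that("delta = 0 equal-prior labels equal the nearest-centroid oracle", {
  set.seed(59)
  dat <- make_class_data(n_per_class = 20, p = 15, planted = 1:5,
                         shift = 0.6)
  m <- nsc_train(dat$x, dat$y, delta_grid = 0)
  toys <- matrix(rnorm(200 * 15, 0, 0.6), 200, 15)
  oracle <- oracle_nearest_centroid(toys, m$class_centroids,
                                    m$pooled_sd + m$s0, m$priors,
                                    rownames(m$class_centroids))
  mine <- apply(toys, 1, function(v) {
    p <- nsc_score(m, v)$posterior
    names(p)[which.max(p)]
  })
  expect_identical(unname(mine), unname(oracle))
})

test_that("cohort classification summarizes class counts with percentages", {
  set.seed(60)
  dat <- make_class_data(n_per_class = 20, p = 30, planted = 1:10)
  m <- nsc_train(dat$x, dat$y, delta_grid = 0)
  # 61 profiles at the negative centroid, 68 at the positive centroid
  feats <- rbind(
    matrix(rep(m$class_centroids["non-BRCA1-like", ], each = 61), nrow = 61),
    matrix(rep(m$class_centroids["BRCA1-like", ], each = 68), nrow = 68))
  out <- classify_cohort(m, feats)
  s <- out$summary
  expect_equal(s$n[s$label == "non-BRCA1-like"], 61L)
  expect_equal(s$pct[s$label == "non-BRCA1-like"], 47.3)
  expect_equal(s$pct[s$label == "BRCA1-like"], 52.7)

  empty <- classify_cohort(m, list())
  expect_equal(nrow(empty$results), 0)

  same <- classify_cohort(m, feats[rep(1, 5), ])
  expect_equal(length(unique(same$results$label)), 1)
})

test_that("model serialization round-trips through JSON", {
  set.seed(62)
  dat <- make_class_data(n_per_class = 10, p = 12, planted = 1:4)
  m <- nsc_train(dat$x, dat$y, seed = 63)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  v <- dat$x[7, ]
  expect_equal(nsc_score(m2, v)$score, nsc_score(m, v)$score,
               tolerance = 1e-12)
  expect_equal(m2$delta, m$delta)
  expect_equal(m2$threshold, m$threshold)
})
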