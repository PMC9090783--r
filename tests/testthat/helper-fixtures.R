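# Fixture builders and independent oracles shared across test files.

# flat annotated bin grid with full control over gc/mappability
flat_bins <- function(n, chrom = "1", bin_size = 20000, gc = NULL,
                      mappability = 1, blacklisted = FALSE) {
  starts <- (seq_len(n) - 1) * bin_size
  data.frame(chrom = rep(chrom, n), start = starts, end = starts + bin_size,
             gc = if (is.null(gc)) rep(0.5, n) else rep_len(gc, n),
             mappability = rep_len(mappability, n),
             blacklisted = rep_len(blacklisted, n),
             stringsAsFactors = FALSE)
}

# standard 4x25Mb genome used by end-to-end pipeline tests (5000 bins)
standard_genome <- function(n_chrom = 4, chrom_mb = 25) {
  sim_genome(stats::setNames(rep(chrom_mb * 1e6, n_chrom),
                             as.character(seq_len(n_chrom))))
}

# two-class gaussian feature data with planted discriminative features
make_class_data <- function(n_per_class = 40, p = 200, planted = 1:30,
                            shift = 1.0, sd = 0.3) {
  x <- matrix(rnorm(2 * n_per_class * p, 0, sd), 2 * n_per_class, p)
  x[(n_per_class + 1):(2 * n_per_class), planted] <-
    x[(n_per_class + 1):(2 * n_per_class), planted] + shift
  list(x = x,
       y = rep(c("non-BRCA1-like", "BRCA1-like"), each = n_per_class),
       planted = planted)
}

# brute-force nearest-centroid oracle: diagonal Mahalanobis distance with
# scale (s + s0), minus 2 log prior; returns class labels
oracle_nearest_centroid <- function(x, centroids, scale, priors, classes) {
  apply(x, 1, function(v) {
    d <- vapply(seq_len(nrow(centroids)), function(j)
      sum((v - centroids[j, ])^2 / scale^2) - 2 * log(priors[j]),
      numeric(1))
    classes[which.min(d)]
  })
}

# Breslow partial log-likelihood for one binary covariate; independent of
# the survival package
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# hand-rolled product-limit estimator (right-censored), returns S(t)
km_oracle <- function(t_eval, time, event) {
  s <- 1
  for (tt in sort(unique(time[event == 1]))) {
    if (tt > t_eval) break
    at_risk <- sum(time >= tt)
    d <- sum(time == tt & event == 1)
    s <- s * (1 - d / at_risk)
  }
  s
}

# a contiguous window of `width` bins on one chromosome whose mean GC is
# closest to the genome-wide median: a GC-representative place to plant a
# copy-number aberration so recovery is not confounded with the GC fit's
# sparse tails
gc_neutral_window <- function(bins, chrom = "2", width = 50) {
  idx <- which(bins$chrom == chrom)
  gc_target <- stats::median(bins$gc)
  run_mean <- stats::filter(bins$gc[idx], rep(1 / width, width),
                            sides = 1)
  ends <- which.min(abs(run_mean - gc_target))
  first <- idx[ends - width + 1]
  data.frame(chrom = chrom, start = bins$start[first],
             end = bins$start[first] + width * 2e4, shift = -1.0)
}

# 103 score pairs with marginals split 44/59 and 11 disagreements in each
# direction, so percentile-matched dichotomization at 0.63 yields 81/103
# concordant calls
acceptance_pairs_103 <- function() {
  score_a <- c(seq(0.01, 0.60, length.out = 44),
               seq(0.65, 0.99, length.out = 59))
  b_rank <- integer(103)
  b_rank[1:33] <- 1:33
  b_rank[34:44] <- 45:55
  b_rank[45:55] <- 34:44
  b_rank[56:103] <- 56:103
  data.frame(score_a = score_a, score_b = b_rank)
}

# features of the surviving (non-shrunk) contrast set of a trained model
surviving_features <- function(model) {
  diff <- abs(sweep(model$class_centroids, 2, model$overall_centroid, "-"))
  which(colSums(diff) > 1e-12)
}
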