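# Cross-platform biomarker concordance by percentile-matched
# dichotomization: the DNA-based classifier score carries an established
# cutoff; the second (e.g. an RNA-based BRCAness signature on an arbitrary
# scale) has none, so it is dichotomized at the percentile at which the
# established cutoff falls in the first score's distribution.

#' Percentile of a cutoff within a score distribution
#'
#' Defined by strict "below" counting:
#' `100 * #(scores < cutoff) / n`. With tie-free data this makes the
#' marginal-matching property of [dichotomize_at_percentile()] exact.
#'
#' @param scores Numeric vector, length >= 2.
#' @param cutoff The established cutoff.
#' @return Percentile in `[0, 100]`.
#' @export
percentile_of_cutoff <- function(scores, cutoff) {
  if (length(scores) < 2)
    stop("need at least 2 scores to locate a percentile", call. = FALSE)
  check_number(cutoff, "cutoff")
  100 * mean(scores < cutoff)
}

#' Dichotomize scores at a given percentile
#'
#' The cutoff on the second score is its empirical quantile (linear
#' interpolation, type 7) at the percentile; samples at or above the cutoff
#' are labeled high. The proportion labeled low matches `percentile/100`
#' within `1/n` on tie-free data.
#'
#' @param scores Numeric vector.
#' @param percentile Percentile in `[0, 100]`.
#' @return Logical vector (`TRUE` = high) with attribute `cutoff`.
#' @export
dichotomize_at_percentile <- function(scores, percentile) {
  check_number(percentile, "percentile", 0, 100)
  cutoff <- unname(stats::quantile(scores, percentile / 100, type = 7,
                                   names = FALSE))
  structure(scores >= cutoff, cutoff = cutoff)
}

#' Two-score concordance after percentile-matched dichotomization
#'
#' Dichotomizes `score_a` at its established cutoff, locates that cutoff's
#' percentile, dichotomizes `score_b` at the same percentile of its own
#' distribution, and tabulates the 2x2 agreement.
#'
#' @param pairs `data.frame` with columns `score_a` (the cutoff-bearing
#'   score, in `[0,1]`) and `score_b` (arbitrary scale); optionally
#'   `sample_id`.
#' @param cutoff_a Established cutoff on `score_a` (default 0.63).
#' @return Object of class `concordance_result`: `percentile_used`,
#'   `cutoff_b`, `table` (2x2 counts), `concordant_fraction`, `n`.
#' @export
score_concordance <- function(pairs, cutoff_a = 0.63) {
  stopifnot(is.data.frame(pairs),
            all(c("score_a", "score_b") %in% names(pairs)))
  if (nrow(pairs) < 2)
    stop("need at least 2 score pairs", call. = FALSE)
  if (anyNA(pairs$score_a) || anyNA(pairs$score_b))
    stop("score pairs must be complete (no missing values)", call. = FALSE)
  if ("sample_id" %in% names(pairs) && anyDuplicated(pairs$sample_id))
    stop("sample ids must be unique", call. = FALSE)

  high_a <- pairs$score_a >= cutoff_a
  pct <- percentile_of_cutoff(pairs$score_a, cutoff_a)
  high_b <- dichotomize_at_percentile(pairs$score_b, pct)
  tab <- table(a = factor(high_a, c(FALSE, TRUE), c("low", "high")),
               b = factor(high_b, c(FALSE, TRUE), c("low", "high")))
  structure(list(percentile_used = pct,
                 cutoff_b = attr(high_b, "cutoff"),
                 table = tab,
                 concordant_fraction = (tab["low", "low"] +
                                        tab["high", "high"]) / nrow(pairs),
                 n = nrow(pairs)),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Concordance: %.1f%% (%d/%d)\n",
              100 * x$concordant_fraction,
              x$table["low", "low"] + x$table["high", "high"], x$n))
  cat(sprintf("cutoff percentile %.1f; score_b cutoff %.3g\n",
              x$percentile_used, x$cutoff_b))
  print(x$table)
  invisible(x)
}

# P(Z1 < h, Z2 < h) for standard bivariate normal with correlation rho,
# reduced to a 1-D integral of the conditional normal CDF.
bvn_lower_orthant <- function(h, rho) {
  if (rho >= 1) return(stats::pnorm(h))
  if (rho <= -1) return(max(0, 2 * stats::pnorm(h) - 1))
  stats::integrate(function(z)
    stats::dnorm(z) * stats::pnorm((h - rho * z) / sqrt(1 - rho^2)),
    -Inf, h, rel.tol = 1e-10)$value
}

# theoretical concordant fraction under a Gaussian copula when both scores
# are split at the p-th quantile of their own marginal
copula_concordance <- function(rho, p) {
  h <- stats::qnorm(p)
  both_low <- bvn_lower_orthant(h, rho)
  1 - 2 * (p - both_low)
}

#' Simulate paired biomarker scores with a target concordance
#'
#' Draws latent ranks from a Gaussian copula whose correlation is solved by
#' a root-finder so that, after percentile-matched dichotomization at
#' `cutoff_a`, the concordant fraction converges to `target_concordance`.
#' `score_a` is uniform on `[0,1]` (a calibrated probability score);
#' `score_b` is log-normal on an arbitrary positive scale.
#'
#' @param n Number of pairs (>= 10).
#' @param target_concordance Target concordant fraction in `[0.5, 1]`.
#' @param cutoff_a Established cutoff on `score_a` (default 0.63).
#' @param seed Integer seed.
#' @param meanlog_b,sdlog_b Log-normal parameters of the `score_b` scale.
#' @return `data.frame` (`sample_id`, `score_a`, `score_b`) with the copula
#'   correlation in attribute `rho`.
#' @export
simulate_paired_scores <- function(n, target_concordance, cutoff_a = 0.63,
                                   seed = NULL, meanlog_b = log(6),
                                   sdlog_b = 0.4) {
  if (!is.numeric(n) || n < 10)
    stop("n must be at least 10", call. = FALSE)
  check_number(target_concordance, "target_concordance", 0.5, 1)
  check_number(cutoff_a, "cutoff_a", 0, 1, strict_lower = TRUE)
  if (cutoff_a >= 1) stop("cutoff_a must be in (0, 1)", call. = FALSE)

  p <- cutoff_a  # score_a is uniform, so its cutoff percentile is cutoff_a
  rho <- if (target_concordance >= 1) {
    1
  } else {
    lo <- copula_concordance(-0.9999, p)
    if (target_concordance < lo - 1e-9)
      stop("target_concordance ", target_concordance,
           " is unreachable for cutoff ", cutoff_a, call. = FALSE)
    stats::uniroot(function(r) copula_concordance(r, p) - target_concordance,
                   c(-0.9999, 0.99999), tol = 1e-9)$root
  }
  with_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- if (rho == 1) z1 else rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    data.frame(sample_id = paste0("s", seq_len(n)),
               score_a = stats::pnorm(z1),
               score_b = stats::qlnorm(stats::pnorm(z2), meanlog_b, sdlog_b),
               stringsAsFactors = FALSE) -> out
    attr(out, "rho") <- rho
    out
  })
}
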