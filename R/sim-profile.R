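#' Specify a copy-number class for simulation
#'
#' Describes the copy-number aberration pattern of one tumour class.
#' BRCA1-like tumours are characterised by recurrent genome-wide copy-number
#' aberrations; here the discriminating regions are free simulation
#' parameters, not biological claims about specific loci.
#'
#' @param label Class label, `"BRCA1-like"` or `"non-BRCA1-like"`.
#' @param aberration_regions `data.frame` with columns `chrom`, `start`,
#'   `end`, `shift` (mean log2 shift applied to bins in the region); may have
#'   zero rows.
#' @param segment_rate Expected random breakpoints per 100 Mb.
#' @param noise_sd Per-bin Gaussian sd of the log2 signal.
#' @param segment_shift_sd Sd of the log2 shift of random segments.
#' @return Object of class `cnv_class_spec`.
#' @export
cnv_class_spec <- function(label = c("BRCA1-like", "non-BRCA1-like"),
                           aberration_regions = NULL,
                           segment_rate = 0,
                           noise_sd = 0.1,
                           segment_shift_sd = 0.2) {
  label <- match.arg(label)
  if (is.null(aberration_regions))
    aberration_regions <- data.frame(chrom = character(), start = numeric(),
                                     end = numeric(), shift = numeric())
  stopifnot(is.data.frame(aberration_regions),
            all(c("chrom", "start", "end", "shift") %in%
                  names(aberration_regions)))
  if (nrow(aberration_regions) && !all(is.finite(aberration_regions$shift)))
    stop("aberration region shifts must be finite", call. = FALSE)
  check_number(segment_rate, "segment_rate", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(segment_shift_sd, "segment_shift_sd", lower = 0)
  structure(list(label = label,
                 aberration_regions = aberration_regions,
                 segment_rate = segment_rate,
                 noise_sd = noise_sd,
                 segment_shift_sd = segment_shift_sd),
            class = "cnv_class_spec")
}

#' Simulate a true per-bin log2 copy-number signal
#'
#' The signal is additive: fixed class aberration-region shifts, random
#' segmental shifts (breakpoints arriving at `segment_rate` per 100 Mb, each
#' segment shifted by a Gaussian amount), and per-bin Gaussian noise.
#' Regions that do not overlap the grid are ignored with a warning.
#'
#' @param bins A bin grid (see [make_bin_grid()]).
#' @param spec A [cnv_class_spec()].
#' @param seed Integer seed.
#' @return List with `log2` (numeric per bin) and `breakpoints`
#'   (`data.frame` of `chrom`, `pos` of the random segment boundaries used).
#' @export
simulate_profile <- function(bins, spec, seed = NULL) {
  stopifnot(is.data.frame(bins), nrow(bins) > 0,
            inherits(spec, "cnv_class_spec"))
  n <- nrow(bins)
  signal <- numeric(n)

  regions <- spec$aberration_regions
  if (nrow(regions)) {
    regions$chrom <- normalize_chrom(regions$chrom)
    for (i in seq_len(nrow(regions))) {
      hit <- bins$chrom == regions$chrom[i] &
        bins$start < regions$end[i] & bins$end > regions$start[i]
      hit[is.na(hit)] <- FALSE
      if (!any(hit)) {
        warning("aberration region ", i, " does not overlap the bin grid; ",
                "ignored", call. = FALSE)
        next
      }
      signal[hit] <- signal[hit] + regions$shift[i]
    }
  }

  bkpt <- data.frame(chrom = character(), pos = numeric(),
                     stringsAsFactors = FALSE)
  with_seed(seed, {
    if (spec$segment_rate > 0) {
      for (ch in unique(bins$chrom)) {
        idx <- which(bins$chrom == ch)
        len <- max(bins$end[idx])
        k <- stats::rpois(1, spec$segment_rate * len / 1e8)
        if (k == 0) next
        pos <- sort(stats::runif(k, 0, len))
        shifts <- stats::rnorm(k + 1, 0, spec$segment_shift_sd)
        seg <- findInterval(bins$start[idx], pos) + 1L
        signal[idx] <- signal[idx] + shifts[seg]
        bkpt <- rbind(bkpt, data.frame(chrom = ch, pos = pos,
                                       stringsAsFactors = FALSE))
      }
    }
    if (spec$noise_sd > 0)
      signal <- signal + stats::rnorm(n, 0, spec$noise_sd)
  })
  list(log2 = signal, breakpoints = bkpt)
}

#' Simulate binned read counts with GC and mappability bias
#'
#' Expected count for bin i is
#' `mean_depth * 2^log2_i * mappability_i * exp(b0 + b1*gc_i + b2*gc_i^2)`;
#' realized counts are Poisson (or negative-binomial when `overdispersion`
#' is positive). Blacklisted bins still receive counts — removing them is
#' the profiling pipeline's job, and the simulator must exercise it.
#'
#' @param bins A bin grid.
#' @param true_log2 Per-bin true log2 copy-number signal.
#' @param mean_depth Expected reads per bin at neutral copy number,
#'   mappability 1 and no GC bias; must be positive.
#' @param gc_bias Numeric coefficients `(b0, b1, b2)` of a quadratic in GC
#'   applied on the log scale; shorter vectors are zero-padded.
#' @param overdispersion Gamma-mixing variance; 0 gives pure Poisson.
#' @param seed Integer seed.
#' @return Integer vector of per-bin counts.
#' @export
simulate_counts <- function(bins, true_log2, mean_depth,
                            gc_bias = c(0, 0, 0), overdispersion = 0,
                            seed = NULL) {
  stopifnot(is.data.frame(bins), length(true_log2) == nrow(bins))
  check_number(mean_depth, "mean_depth", lower = 0, strict_lower = TRUE)
  check_number(overdispersion, "overdispersion", lower = 0)
  b <- rep_len(c(gc_bias, 0, 0, 0), 3)
  mu <- mean_depth * 2^true_log2 * bins$mappability *
    exp(b[1] + b[2] * bins$gc + b[3] * bins$gc^2)
  with_seed(seed, {
    if (overdispersion > 0) {
      stats::rnbinom(length(mu), mu = mu, size = 1 / overdispersion)
    } else {
      stats::rpois(length(mu), mu)
    }
  })
}
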