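# Shallow whole-genome copy-number profiling: count reads on a 20 kb
# autosomal bin grid, drop blacklisted and poorly mappable bins, correct
# local GC effects with loess fitted on well-mappable bins, scale
# mappability to reference counts with a through-origin line, and report
# per-bin log2 ratios.

#' Count read starts per bin
#'
#' Assigns each read to the unique bin whose half-open interval
#' `[start, end)` contains its 5' start position. Reads on non-autosomes or
#' outside the grid are dropped and tallied.
#'
#' @param read_starts `data.frame` with columns `chrom` and `pos` (0-based
#'   read start positions).
#' @param bins A bin grid (`chrom`, `start`, `end`, sorted, non-overlapping
#'   within chromosome).
#' @return List with `counts` (integer per bin), `n_assigned`, `n_dropped`
#'   and `n_malformed`.
#' @export
count_reads <- function(read_starts, bins) {
  stopifnot(is.data.frame(bins),
            all(c("chrom", "start", "end") %in% names(bins)))
  if (is.null(read_starts) || nrow(read_starts) == 0) {
    return(list(counts = integer(nrow(bins)), n_assigned = 0L,
                n_dropped = 0L, n_malformed = 0L))
  }
  stopifnot(all(c("chrom", "pos") %in% names(read_starts)))
  pos <- suppressWarnings(as.numeric(read_starts$pos))
  bad <- !is.finite(pos) | pos < 0
  chrom <- normalize_chrom(read_starts$chrom)

  counts <- integer(nrow(bins))
  dropped <- sum(!bad & is.na(chrom))
  keep <- !bad & !is.na(chrom)
  for (ch in unique(bins$chrom)) {
    bidx <- which(bins$chrom == ch)
    p <- pos[keep & chrom == ch]
    if (!length(p)) next
    # bins are sorted and contiguous-or-gapped; locate by start, then check
    # the read actually falls before the bin end
    j <- findInterval(p, bins$start[bidx])
    inside <- j >= 1 & p < bins$end[bidx][pmax(j, 1)]
    dropped <- dropped + sum(!inside)
    tab <- tabulate(j[inside], nbins = length(bidx))
    counts[bidx] <- counts[bidx] + tab
  }
  # reads on chromosomes absent from the grid
  grid_chroms <- unique(bins$chrom)
  dropped <- dropped + sum(keep & !chrom %in% grid_chroms)
  list(counts = counts,
       n_assigned = sum(counts),
       n_dropped = as.integer(dropped),
       n_malformed = as.integer(sum(bad)))
}

#' Bin inclusion mask
#'
#' A bin is analysable iff it is not blacklisted and its reference
#' mappability is at least `min_mappability`. The default 0.2 keeps bins at
#' exactly 0.2 (only mappability strictly below 0.2 is excluded).
#'
#' @param bins A bin grid with `mappability` and `blacklisted` columns.
#' @param min_mappability Inclusive lower mappability bound (default 0.2).
#' @return Logical vector, `TRUE` for analysable bins.
#' @export
filter_bins <- function(bins, min_mappability = 0.2) {
  stopifnot(all(c("mappability", "blacklisted") %in% names(bins)))
  !bins$blacklisted & bins$mappability >= min_mappability
}

#' Loess GC-bias correction
#'
#' Fits a loess curve of count against GC fraction using only masked-in bins
#' with mappability strictly above `fit_mappability` (well-mappable bins
#' give the cleanest GC response), then divides every masked-in bin's count
#' by the fitted value at its GC and multiplies by the fit's mean level so
#' the corrected counts keep the overall scale of the input. Because GC
#' bias acts multiplicatively on read depth, the curve is fitted on the log
#' scale (zero-count bins are left out of the fit but still corrected).
#' Bins whose GC lies outside the fitted range use the fitted value at the
#' nearest fitted GC.
#'
#' @param counts Per-bin counts (numeric).
#' @param bins A bin grid with a `gc` column.
#' @param mask Logical inclusion mask (see [filter_bins()]).
#' @param span Loess span (default 0.3); degree-2 local fit with the usual
#'   tricube weights.
#' @param fit_mappability Strict lower mappability bound for the fitting
#'   subset (default 0.8).
#' @param min_fit_bins Minimum number of fitting bins required.
#' @return Numeric vector of corrected counts (`NA` outside the mask).
#' @export
loess_gc_correct <- function(counts, bins, mask, span = 0.3,
                             fit_mappability = 0.8, min_fit_bins = 50L) {
  stopifnot(length(counts) == nrow(bins), length(mask) == nrow(bins))
  fit_idx <- which(mask & bins$mappability > fit_mappability & counts > 0)
  if (length(fit_idx) < min_fit_bins)
    stop("only ", length(fit_idx), " masked-in bins with mappability > ",
         fit_mappability, " and non-zero counts; at least ", min_fit_bins,
         " are required - provide a larger input", call. = FALSE)

  df <- data.frame(ly = log(as.numeric(counts[fit_idx])),
                   gc = bins$gc[fit_idx])
  # robust (symmetric) loss so focal copy-number aberrations do not drag
  # the GC curve toward themselves
  fit <- stats::loess(ly ~ gc, data = df, span = span, degree = 2,
                      family = "symmetric",
                      control = stats::loess.control(surface = "direct"))
  gc_rng <- range(df$gc)
  mean_level <- mean(exp(stats::fitted(fit)))

  corrected <- rep(NA_real_, length(counts))
  idx <- which(mask)
  gc_eval <- pmin(pmax(bins$gc[idx], gc_rng[1]), gc_rng[2])
  pred <- exp(stats::predict(fit, newdata = data.frame(gc = gc_eval)))
  corrected[idx] <- counts[idx] / pred * mean_level
  corrected
}

#' Through-origin mappability scaling slope
#'
#' Masked-in bins are grouped into equal-width mappability intervals; each
#' non-empty interval contributes its centre (median mappability, median
#' GC-corrected count) weighted by its occupancy, and a weighted
#' least-squares line through the origin is fitted over the centres. The
#' slope converts mappability into an expected reference count.
#'
#' @param corrected GC-corrected counts ([loess_gc_correct()]).
#' @param bins A bin grid.
#' @param mask Logical inclusion mask.
#' @param n_groups Number of equal-width mappability intervals on
#'   `[min_mappability, 1]` (default 20).
#' @param min_mappability Lower edge of the grouping range (default 0.2).
#' @return Positive slope (reference counts per unit mappability).
#' @export
fit_reference_slope <- function(corrected, bins, mask, n_groups = 20L,
                                min_mappability = 0.2) {
  idx <- which(mask & is.finite(corrected))
  if (!length(idx)) stop("no usable bins for slope fitting", call. = FALSE)
  mapp <- bins$mappability[idx]
  if (length(unique(floor(pmin(mapp, 0.999) * 10))) < 3)
    stop("masked-in bins span fewer than 3 distinct mappability deciles; ",
         "cannot fit the reference slope", call. = FALSE)

  breaks <- seq(min_mappability, 1, length.out = n_groups + 1)
  grp <- cut(mapp, breaks = breaks, include.lowest = TRUE)
  centers <- lapply(split(idx, grp), function(ii) {
    if (!length(ii)) return(NULL)
    c(x = stats::median(bins$mappability[ii]),
      y = stats::median(corrected[ii]),
      w = length(ii))
  })
  centers <- do.call(rbind, centers[!vapply(centers, is.null, logical(1))])
  x <- centers[, "x"]; y <- centers[, "y"]; w <- centers[, "w"]
  slope <- sum(w * x * y) / sum(w * x^2)
  if (!is.finite(slope) || slope <= 0)
    stop("non-positive reference slope; input counts look pathological",
         call. = FALSE)
  slope
}

#' Log2 copy-number profile
#'
#' For each masked-in bin the expected reference count is
#' `slope * mappability`; the profile value is
#' `log2(corrected / expected)`. Bins with non-positive corrected counts are
#' removed from the mask rather than given infinite ratios — pseudo-counts
#' would distort low-count bins.
#'
#' @param corrected GC-corrected counts.
#' @param bins A bin grid.
#' @param mask Logical inclusion mask.
#' @param slope Reference scaling slope ([fit_reference_slope()]).
#' @param provenance Optional list recorded on the result.
#' @return A `genomic_profile`: `data.frame` with `chrom`, `start`, `end`,
#'   `log2_ratio`, `included` and a `provenance` attribute.
#' @export
log2_profile <- function(corrected, bins, mask, slope, provenance = list()) {
  check_number(slope, "slope", lower = 0, strict_lower = TRUE)
  included <- mask & is.finite(corrected) & corrected > 0
  ratio <- rep(NA_real_, nrow(bins))
  expected <- slope * bins$mappability[included]
  ratio[included] <- log2(corrected[included] / expected)
  out <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                    log2_ratio = ratio, included = included,
                    stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  class(out) <- c("genomic_profile", "data.frame")
  out
}

#' Run the full copy-number profiling pipeline
#'
#' Deterministic composition: count (if read starts are given) -> filter ->
#' loess GC correction -> through-origin mappability slope -> log2 ratios.
#' Filter thresholds, loess span and the fitted slope are recorded in the
#' profile's provenance.
#'
#' @param bins A bin grid.
#' @param counts Per-bin counts; alternatively supply `read_starts`.
#' @param read_starts Read start positions (see [count_reads()]).
#' @param span Loess span.
#' @param min_mappability Inclusive mappability filter threshold.
#' @param fit_mappability Strict threshold for the GC-fit subset.
#' @return A `genomic_profile`.
#' @export
run_pipeline <- function(bins, counts = NULL, read_starts = NULL,
                         span = 0.3, min_mappability = 0.2,
                         fit_mappability = 0.8) {
  if (is.null(counts)) {
    if (is.null(read_starts))
      stop("supply either counts or read_starts", call. = FALSE)
    counts <- count_reads(read_starts, bins)$counts
  }
  mask <- filter_bins(bins, min_mappability)
  corrected <- loess_gc_correct(counts, bins, mask, span = span,
                                fit_mappability = fit_mappability)
  slope <- fit_reference_slope(corrected, bins, mask,
                               min_mappability = min_mappability)
  log2_profile(corrected, bins, mask, slope,
               provenance = list(span = span,
                                 min_mappability = min_mappability,
                                 fit_mappability = fit_mappability,
                                 slope = slope))
}
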