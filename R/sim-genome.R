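#' Define a synthetic autosomal genome
#'
#' A lightweight description of an autosome-only genome used by the
#' synthetic-data generators: named chromosome lengths plus the bin size of
#' the counting grid (20 kb by default, the resolution used for shallow
#' whole-genome copy-number profiling).
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#'   Names must be autosomes `1`-`22`, optionally `chr`-prefixed.
#' @param bin_size Bin width in bp (default 20000).
#' @return An object of class `sim_genome`.
#' @examples
#' sim_genome(c(chr1 = 1e6, chr2 = 5e5))
#' @export
sim_genome <- function(chrom_lengths, bin_size = 20000L) {
  if (length(chrom_lengths) == 0 || is.null(names(chrom_lengths)))
    stop("chrom_lengths must be a named vector", call. = FALSE)
  if (anyDuplicated(names(chrom_lengths)))
    stop("chromosome names must be unique", call. = FALSE)
  assert_autosomes(names(chrom_lengths))
  if (!all(is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("all chromosome lengths must be > 0", call. = FALSE)
  check_number(bin_size, "bin_size", lower = 0, strict_lower = TRUE)
  structure(
    list(chrom_lengths = chrom_lengths, bin_size = as.integer(bin_size)),
    class = "sim_genome"
  )
}

#' Generate an annotated bin grid
#'
#' Tiles each chromosome with half-open bins `[k*bin_size, (k+1)*bin_size)`
#' (the final bin truncated at the chromosome end) and attaches synthetic
#' per-bin annotation: a spatially smooth GC fraction, a mappability track
#' with configurable low (<0.2) and high (>0.8) tails, and blacklist flags.
#' GC is produced as a moving average of uniform noise (window 25 bins)
#' rescaled to `[0.3, 0.7]`, which gives realistic spatial autocorrelation
#' without external tracks.
#'
#' @param genome A [sim_genome()].
#' @param seed Integer seed; the grid is reproducible given the seed.
#' @param frac_low_mapp Fraction of bins with mappability below 0.2.
#' @param frac_high_mapp Fraction of bins with mappability above 0.8.
#' @param frac_blacklist Fraction of bins flagged as blacklisted.
#' @param gc_window Moving-average window (bins) for the GC process.
#' @param gc_range Length-2 numeric range the GC track is rescaled to.
#' @return A `data.frame` of class `bin_grid` with columns `chrom`, `start`,
#'   `end`, `gc`, `mappability`, `blacklisted`.
#' @export
make_bin_grid <- function(genome, seed = NULL,
                          frac_low_mapp = 0.02,
                          frac_high_mapp = 0.85,
                          frac_blacklist = 0.01,
                          gc_window = 25L,
                          gc_range = c(0.3, 0.7)) {
  stopifnot(inherits(genome, "sim_genome"))
  check_number(frac_low_mapp, "frac_low_mapp", 0, 1)
  check_number(frac_high_mapp, "frac_high_mapp", 0, 1)
  if (frac_low_mapp + frac_high_mapp > 1)
    stop("frac_low_mapp + frac_high_mapp must not exceed 1", call. = FALSE)
  check_number(frac_blacklist, "frac_blacklist", 0, 1)

  bs <- genome$bin_size
  pieces <- lapply(names(genome$chrom_lengths), function(ch) {
    len <- genome$chrom_lengths[[ch]]
    starts <- seq.int(0L, len - 1L, by = bs)
    data.frame(chrom = normalize_chrom(ch),
               start = starts,
               end = pmin(starts + bs, len),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  n <- nrow(bins)

  with_seed(seed, {
    # smooth GC per chromosome, rescaled globally to gc_range
    gc_raw <- unlist(lapply(split(seq_len(n), bins$chrom)[unique(bins$chrom)],
                            function(idx) {
      m <- length(idx)
      u <- stats::runif(m + gc_window - 1)
      as.numeric(stats::filter(u, rep(1 / gc_window, gc_window),
                               sides = 1))[gc_window:(m + gc_window - 1)]
    }), use.names = FALSE)
    rng <- range(gc_raw)
    gc <- if (diff(rng) > 0) {
      gc_range[1] + (gc_raw - rng[1]) / diff(rng) * diff(gc_range)
    } else {
      rep(mean(gc_range), n)
    }

    band <- sample(c("low", "mid", "high"), n, replace = TRUE,
                   prob = c(frac_low_mapp,
                            1 - frac_low_mapp - frac_high_mapp,
                            frac_high_mapp))
    mapp <- numeric(n)
    mapp[band == "low"]  <- stats::runif(sum(band == "low"), 0, 0.2)
    mapp[band == "mid"]  <- stats::runif(sum(band == "mid"), 0.2, 0.8)
    mapp[band == "high"] <- stats::runif(sum(band == "high"), 0.8, 1)

    bins$gc <- gc
    bins$mappability <- mapp
    bins$blacklisted <- stats::runif(n) < frac_blacklist
  })
  class(bins) <- c("bin_grid", "data.frame")
  bins
}
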