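# Plain-text readers and writers: BED intervals, bin-grid / count / profile
# TSVs, cohort CSVs, classifier models as JSON, and provenance sidecars.
# Everything is diffable text; no binary formats.

#' Read a BED file of intervals
#'
#' 0-based half-open intervals; `track`, `browser` and `#` comment lines
#' are skipped; a malformed line raises an error naming its line number.
#'
#' @param path Path to a BED file.
#' @return `data.frame` with `chrom`, `start`, `end` (plus `name` when a
#'   4th column is present).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                    name = character(), stringsAsFactors = FALSE)
  rows <- vector("list", sum(keep))
  ri <- 0L
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (length(f) < 3 || is.na(start) || is.na(end) || start >= end)
      stop("malformed BED line ", i, " in ", path, call. = FALSE)
    ri <- ri + 1L
    rows[[ri]] <- data.frame(chrom = f[1], start = start, end = end,
                             name = if (length(f) >= 4) f[4] else
                               NA_character_,
                             stringsAsFactors = FALSE)
  }
  if (ri == 0L) return(out)
  do.call(rbind, rows[seq_len(ri)])
}

#' Mark bins overlapping blacklist intervals
#'
#' Any overlap between a bin and a blacklist interval sets the bin's
#' `blacklisted` flag.
#'
#' @param bins A bin grid.
#' @param blacklist `data.frame` of intervals (`chrom`, `start`, `end`),
#'   e.g. from [read_bed()].
#' @return The bin grid with an updated `blacklisted` column.
#' @export
apply_blacklist <- function(bins, blacklist) {
  bl_chrom <- normalize_chrom(blacklist$chrom)
  flag <- bins$blacklisted %||% rep(FALSE, nrow(bins))
  if (is.null(bins$blacklisted)) bins$blacklisted <- flag
  for (i in seq_len(nrow(blacklist))) {
    hit <- bins$chrom == bl_chrom[i] &
      bins$start < blacklist$end[i] & bins$end > blacklist$start[i]
    bins$blacklisted[which(hit)] <- TRUE
  }
  bins
}

#' @rdname io_tables
#' @export
write_bin_grid <- function(bins, path, config = NULL) {
  df <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                   gc = bins$gc, mappability = bins$mappability,
                   blacklist = as.integer(bins$blacklisted))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(config)) write_provenance(path, config)
  invisible(path)
}

#' Tabular readers and writers
#'
#' Bin grids travel as 6-column TSV (`chrom`, `start`, `end`, `gc`,
#' `mappability`, `blacklist` 0/1), counts as 4-column TSV, profiles as
#' 5-column TSV (`chrom`, `start`, `end`, `log2_ratio`, `included`), and
#' cohorts as headed CSV. Writers accept a `config` list which is written
#' to a `<path>.json` provenance sidecar.
#'
#' @param bins,counts,profile,records The object to write.
#' @param path File path.
#' @param config Optional list recorded as a JSON sidecar.
#' @name io_tables
#' @export
read_bin_grid <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(chrom = "character"))
  bins <- data.frame(chrom = normalize_chrom(df$chrom), start = df$start,
                     end = df$end, gc = df$gc,
                     mappability = df$mappability,
                     blacklisted = df$blacklist > 0,
                     stringsAsFactors = FALSE)
  class(bins) <- c("bin_grid", "data.frame")
  bins
}

#' @rdname io_tables
#' @export
write_counts <- function(bins, counts, path, config = NULL) {
  df <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                   count = counts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(config)) write_provenance(path, config)
  invisible(path)
}

#' @rdname io_tables
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(chrom = "character"))
  df$chrom <- normalize_chrom(df$chrom)
  df
}

#' @rdname io_tables
#' @export
write_profile <- function(profile, path, config = NULL) {
  df <- data.frame(chrom = profile$chrom, start = profile$start,
                   end = profile$end, log2_ratio = profile$log2_ratio,
                   included = as.integer(profile$included))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(config))
    write_provenance(path, config)
  else if (!is.null(attr(profile, "provenance")))
    write_provenance(path, attr(profile, "provenance"))
  invisible(path)
}

#' @rdname io_tables
#' @export
read_profile <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(chrom = "character"))
  out <- data.frame(chrom = normalize_chrom(df$chrom), start = df$start,
                    end = df$end, log2_ratio = df$log2_ratio,
                    included = df$included > 0, stringsAsFactors = FALSE)
  class(out) <- c("genomic_profile", "data.frame")
  out
}

#' @rdname io_tables
#' @export
write_cohort <- function(records, path, config = NULL) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  if (!is.null(config)) write_provenance(path, config)
  invisible(path)
}

#' @rdname io_tables
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("arm" %in% names(df)) df$arm <- factor(df$arm, ARM_LEVELS)
  if ("marker" %in% names(df)) df$marker <- factor(df$marker, CLASS_LEVELS)
  df
}

# provenance sidecar: <path>.json describing how a file was generated
write_provenance <- function(path, config) {
  side <- paste0(path, ".json")
  payload <- c(list(generated_by = "brcalike",
                    version = as.character(utils::packageVersion("brcalike"))),
               config)
  jsonlite::write_json(payload, side, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(side)
}

#' Serialize and restore a centroid model as JSON
#'
#' The model file carries the feature grid, overall and class centroids,
#' pooled sds, the fudge constant `s0`, the chosen shrinkage `delta`, class
#' priors, the decision threshold, and training metadata.
#'
#' @param model A `centroid_model`.
#' @param path JSON file path.
#' @return `write_model` returns `path`; `read_model` a `centroid_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "centroid_model"))
  payload <- list(
    format = "brcalike-centroid-model",
    classes = model$classes,
    feature_grid = model$feature_grid,
    overall_centroid = model$overall_centroid,
    class_centroids = stats::setNames(
      lapply(seq_along(model$classes),
             function(j) unname(model$class_centroids[j, ])),
      model$classes),
    pooled_sd = model$pooled_sd,
    s0 = model$s0,
    delta = model$delta,
    priors = as.list(model$priors),
    threshold = model$threshold,
    n_features_used = model$n_features_used,
    n_train = as.list(model$n_train)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "brcalike-centroid-model"))
    stop(path, " is not a centroid model file", call. = FALSE)
  cent <- do.call(rbind, p$class_centroids[p$classes])
  structure(list(feature_grid = as.data.frame(p$feature_grid),
                 overall_centroid = as.numeric(p$overall_centroid),
                 class_centroids = cent,
                 pooled_sd = as.numeric(p$pooled_sd),
                 s0 = p$s0,
                 delta = p$delta,
                 priors = unlist(p$priors)[p$classes],
                 threshold = p$threshold,
                 classes = p$classes,
                 n_features_used = p$n_features_used,
                 cv = NULL,
                 n_train = unlist(p$n_train)),
            class = "centroid_model")
}
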