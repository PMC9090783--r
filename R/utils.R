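# Internal helpers shared across modules.

# Autosome naming: accept "1".."22" with or without a "chr" prefix and
# normalize to the bare number. Anything else (sex chromosomes, contigs)
# is rejected by callers via is.na().
normalize_chrom <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom))
  x[!x %in% as.character(1:22)] <- NA_character_
  x
}

assert_autosomes <- function(chrom) {
  norm <- normalize_chrom(chrom)
  if (anyNA(norm)) {
    bad <- unique(as.character(chrom)[is.na(norm)])
    stop("non-autosome chromosome name(s): ", paste(bad, collapse = ", "),
         " (autosomes 1-22, optionally 'chr'-prefixed, are allowed)",
         call. = FALSE)
  }
  norm
}

# Evaluate `expr` under a fixed RNG seed without touching global RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# scalar checks -----------------------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(name, " must be a single finite number", call. = FALSE)
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    stop(name, " must be in ", if (strict_lower) "(" else "[", lower, ", ",
         upper, "]", call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
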