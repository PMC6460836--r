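#' @importFrom rlang abort warn .data
#' @importFrom dplyr %>%
NULL

# round half-up (base round() is half-even); reporting convention for percentages
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# derive a per-sample RNG seed from a master seed; stays below 2^31
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 16807) %% 2147483647)
}

assert_fragments <- function(records, truth_ok = TRUE) {
  needed <- c("chrom", "start", "length", "is_duplicate", "is_unique_mapping")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    abort(paste0("fragment table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(records) > 0 && any(records$length < 0)) {
    abort("malformed fragment table: negative fragment length")
  }
  invisible(records)
}

# exact hashable key for (chrom, start, length); doubles stay exact below 2^53
fragment_key <- function(records) {
  ci <- as.double(match(records$chrom, unique(records$chrom)))
  ci * 1e13 + as.double(records$start) * 1e3 + as.double(records$length)
}
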