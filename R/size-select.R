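#' In silico size selection
#'
#' Retains exactly the fragments with `length < cutoff` (strict; default
#' 160 bp). Because fetal cfDNA is systematically shorter than maternal
#' cfDNA, this enriches the fetal component of the library.
#'
#' @param records fragment tibble.
#' @param cutoff length cutoff in bp; fragments strictly shorter are kept.
#' @return The retained subset of `records`.
#' @examples
#' gm <- genome_model()
#' fr <- filter_reads(simulate_sample(gm, sample_truth(0.1, n_fragments = 1e4)))
#' nrow(size_select(fr)) / nrow(fr)
#' @export
size_select <- function(records, cutoff = 160) {
  assert_fragments(records)
  if (cutoff <= 0) abort("cutoff must be > 0")
  records[records$length < cutoff, ]
}

LENGTH_BIN_EDGES <- seq(100, 200, by = 10)

#' Per-length-bin chrY-fraction fold change
#'
#' Pools male-fetus samples into mixed sets (default 100 samples per set),
#' splits reads into the ten half-open length bins \[100,110) ... \[190,200),
#' and computes each bin's chromosome-Y read fraction and its fold change
#' relative to the pooled (all-length) chrY fraction. The chrY read
#' fraction proxies the fetal fraction in a male-fetus pregnancy, so the
#' fold-change profile shows where in the length spectrum fetal DNA is
#' concentrated. Reads outside \[100,200) contribute to the pooled fraction
#' but not to any bin.
#'
#' @param cohort a cohort tibble from [simulate_cohort()] (uses the
#'   `fragments` list-column), or a plain list of fragment tibbles.
#' @param group_size samples per mixed set.
#' @param method `"mixed"`: average fold changes across mixed sets (one
#'   profile per set, then mean); `"pooled"`: single profile over all reads.
#' @return A tibble of class `ff_foldchange`: one row per length bin with
#'   `bin`, `lo`, `hi`, `n_reads`, `n_chry`, `chry_fraction`,
#'   `fold_change` (NA where a bin is empty), plus attribute
#'   `pooled_chry_fraction`.
#' @export
binwise_ff_foldchange <- function(cohort, group_size = 100,
                                  method = c("mixed", "pooled")) {
  method <- match.arg(method)
  frags <- if (is.data.frame(cohort)) cohort$fragments else cohort
  if (length(frags) < 1) abort("need at least one sample")
  groups <- if (method == "pooled") list(seq_along(frags)) else
    split(seq_along(frags), (seq_along(frags) - 1) %/% group_size)

  per_group <- purrr::map(groups, function(idx) {
    reads <- dplyr::bind_rows(frags[idx])
    pooled <- mean(reads$chrom == "chrY")
    if (pooled <= 0) abort("pooled chrY fraction is zero; need male-fetus samples")
    bin <- findInterval(reads$length, LENGTH_BIN_EDGES,
                        rightmost.closed = FALSE)
    inside <- bin >= 1 & reads$length < 200
    tab <- tibble::tibble(bin = bin[inside], y = reads$chrom[inside] == "chrY") %>%
      dplyr::group_by(.data$bin) %>%
      dplyr::summarise(n_reads = dplyr::n(), n_chry = sum(.data$y),
                       .groups = "drop")
    full <- tibble::tibble(bin = 1:10) %>%
      dplyr::left_join(tab, by = "bin") %>%
      dplyr::mutate(
        n_reads = dplyr::coalesce(.data$n_reads, 0L),
        n_chry = dplyr::coalesce(.data$n_chry, 0L),
        chry_fraction = ifelse(.data$n_reads > 0,
                               .data$n_chry / .data$n_reads, NA_real_),
        fold_change = .data$chry_fraction / pooled
      )
    attr(full, "pooled") <- pooled
    full
  })

  pooled_frac <- mean(purrr::map_dbl(per_group, attr, "pooled"))
  out <- dplyr::bind_rows(per_group) %>%
    dplyr::group_by(.data$bin) %>%
    dplyr::summarise(
      n_reads = sum(.data$n_reads), n_chry = sum(.data$n_chry),
      chry_fraction = mean(.data$chry_fraction, na.rm = FALSE),
      fold_change = mean(.data$fold_change, na.rm = FALSE),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      lo = LENGTH_BIN_EDGES[.data$bin],
      hi = LENGTH_BIN_EDGES[.data$bin + 1],
      bin = sprintf("[%d,%d)", .data$lo, .data$hi)
    ) %>%
    dplyr::select("bin", "lo", "hi", "n_reads", "n_chry",
                  "chry_fraction", "fold_change")
  attr(out, "pooled_chry_fraction") <- pooled_frac
  class(out) <- c("ff_foldchange", class(out))
  out
}
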