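#' Post-alignment read filters producing unique reads
#'
#' Applies, in order: (1) removal of reads shorter than `min_length`
#' (default 50 bp), (2) removal of non-unique mappers, (3) removal of
#' duplicates, where a duplicate is any record pre-flagged as such or any
#' repeat of an already-seen (chrom, start, length) key. The surviving
#' records are the "unique reads" all downstream stages operate on. The
#' removal report is attached as the `"filter_report"` attribute and can be
#' retrieved with [filter_report()], keeping the filtered table pipeable.
#'
#' @param records fragment tibble (see [simulate_sample()] /
#'   [read_fragments()]).
#' @param min_length minimum fragment length retained (bp).
#' @return The filtered fragment tibble, with attribute `filter_report`: a
#'   one-row tibble with `n_input`, `n_short_removed`, `n_multimap_removed`,
#'   `n_dup_removed`, `n_unique`.
#' @examples
#' gm <- genome_model()
#' fr <- simulate_sample(gm, sample_truth(0.1, n_fragments = 1e4))
#' filtered <- filter_reads(fr)
#' filter_report(filtered)
#' @export
filter_reads <- function(records, min_length = 50) {
  assert_fragments(records)
  n_input <- nrow(records)

  keep_len <- records$length >= min_length
  records <- records[keep_len, ]
  n_short <- n_input - nrow(records)

  keep_uniq <- records$is_unique_mapping
  records <- records[keep_uniq, ]
  n_multi <- sum(!keep_uniq)

  # flagged duplicates go first, then key-based dedup among the remainder:
  # this keeps the unique-read count invariant under record permutation
  flagged <- records$is_duplicate
  records <- records[!flagged, ]
  key_dup <- duplicated(fragment_key(records))
  records <- records[!key_dup, ]
  n_dup <- sum(flagged) + sum(key_dup)

  report <- tibble::tibble(
    n_input = n_input, n_short_removed = n_short,
    n_multimap_removed = n_multi, n_dup_removed = n_dup,
    n_unique = nrow(records)
  )
  stopifnot(report$n_unique ==
              n_input - n_short - n_multi - n_dup)
  attr(records, "filter_report") <- report
  records
}

#' @rdname filter_reads
#' @param filtered a tibble returned by [filter_reads()].
#' @export
filter_report <- function(filtered) {
  rep <- attr(filtered, "filter_report")
  if (is.null(rep)) abort("no filter report attached; run filter_reads() first")
  rep
}
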