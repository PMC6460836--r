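#' Chromosome ratio from a corrected bin table
#'
#' Ratio of summed corrected counts on a chromosome's unmasked bins to the
#' summed corrected counts on all unmasked autosomal bins. On an
#' uncorrected table (no `corrected` column) raw counts are used.
#'
#' @param table bin table from [gc_correct()] (or [bin_counts()]).
#' @param chrom chromosome name.
#' @return The ratio (scalar).
#' @export
chromosome_ratio <- function(table, chrom) {
  counts <- if ("corrected" %in% names(table)) table$corrected else
    table$raw_count
  masked <- if ("masked" %in% names(table)) table$masked else
    rep(FALSE, nrow(table))
  use <- !masked
  num <- sum(counts[use & table$chrom == chrom])
  den <- sum(counts[use & table$chrom %in% AUTOSOMES])
  if (!any(use & table$chrom == chrom)) {
    abort(paste0("no unmasked bins on ", chrom))
  }
  if (den == 0) abort("zero autosomal denominator")
  num / den
}

#' Build a euploid reference for z-scoring
#'
#' Per-chromosome mean and sample SD (n-1 denominator) of chromosome
#' ratios across euploid control samples. The reference must be matched to
#' the test protocol (same enrichment mode and comparable depth), since
#' size selection shifts both the mean ratio and its spread.
#'
#' @param tables list of corrected bin tables of euploid control samples.
#' @param chroms chromosomes to reference (default 13, 18, 21).
#' @param min_samples minimum number of reference samples.
#' @return Object of class `nips_reference`: tibble with `chrom`, `mu`,
#'   `sd`, `n`.
#' @export
build_reference <- function(tables, chroms = c("chr13", "chr18", "chr21"),
                            min_samples = 20) {
  if (length(tables) < min_samples) {
    abort(paste0("need at least ", min_samples, " euploid reference samples"))
  }
  ratios <- purrr::map_dfr(chroms, function(ch) {
    r <- purrr::map_dbl(tables, chromosome_ratio, chrom = ch)
    tibble::tibble(chrom = ch, mu = mean(r), sd = stats::sd(r),
                   n = length(r))
  })
  if (any(ratios$sd <= 0)) {
    abort("degenerate reference: zero SD of chromosome ratio")
  }
  class(ratios) <- c("nips_reference", class(ratios))
  ratios
}

#' @export
print.nips_reference <- function(x, ...) {
  cat("<nips_reference> built from", x$n[1], "euploid samples\n")
  print(tibble::as_tibble(x))
  invisible(x)
}

#' Chromosome-ratio z-score
#'
#' `z = (ratio - mu_c) / sd_c` against the euploid reference.
#'
#' @param ratio observed chromosome ratio.
#' @param reference a [build_reference()] object.
#' @param chrom chromosome name.
#' @return The z-score (scalar).
#' @export
z_score <- function(ratio, reference, chrom) {
  i <- match(chrom, reference$chrom)
  if (is.na(i)) abort(paste0(chrom, " not present in the reference"))
  (ratio - reference$mu[i]) / reference$sd[i]
}

# decision rule shared by call_sample() and direct z-score scoring:
# no-call on QC failure, else positive iff any tested z strictly exceeds
# z_cutoff
decide_call <- function(z, ff, n_unique, min_reads, ff_floor = 0.04,
                        z_cutoff = 3, ff_predictable = TRUE) {
  if (!is.null(n_unique) && n_unique < min_reads) {
    return(list(decision = "no_call", reason = "low_reads", positive = ""))
  }
  if (!ff_predictable || is.na(ff)) {
    return(list(decision = "no_call", reason = "ff_unpredictable",
                positive = ""))
  }
  if (ff < ff_floor) {
    return(list(decision = "no_call", reason = "low_ff", positive = ""))
  }
  pos <- names(z)[z > z_cutoff]
  if (length(pos) > 0) {
    list(decision = "positive", reason = "",
         positive = paste(pos, collapse = ","))
  } else {
    list(decision = "negative", reason = "", positive = "")
  }
}

#' Call a sample from its corrected bin table
#'
#' Computes z-scores for the tested chromosomes and applies the decision
#' rule: no-call when unique reads fall below `min_reads`, when the fetal
#' fraction is below `ff_floor` (default 4%) or is unpredictable;
#' otherwise positive for every tested chromosome with `z > z_cutoff`
#' (strictly; default 3), else negative.
#'
#' @param table corrected bin table of the test sample.
#' @param reference a [build_reference()] object.
#' @param ff fetal-fraction estimate (proportion), or `NA`.
#' @param n_unique unique read count of the sample (post-filter, and
#'   post-selection in enriched mode).
#' @param min_reads minimum unique reads ([scaled_min_reads()] for the
#'   genome in use).
#' @param ff_floor fetal-fraction floor.
#' @param z_cutoff z-score cutoff (strict inequality).
#' @param ff_predictable whether the fetal-fraction estimate passed its
#'   consistency check.
#' @param sample_id identifier.
#' @return One-row tibble: `sample_id`, `z_chr13`, `z_chr18`, `z_chr21`
#'   (as available), `ff`, `n_unique`, `decision`, `positive_for`,
#'   `no_call_reason`.
#' @export
call_sample <- function(table, reference, ff, n_unique, min_reads,
                        ff_floor = 0.04, z_cutoff = 3, ff_predictable = TRUE,
                        sample_id = table$sample_id[1]) {
  z <- vapply(reference$chrom, function(ch) {
    z_score(chromosome_ratio(table, ch), reference, ch)
  }, double(1))
  names(z) <- reference$chrom
  d <- decide_call(z, ff, n_unique, min_reads, ff_floor, z_cutoff,
                   ff_predictable)
  out <- tibble::as_tibble(as.list(stats::setNames(z, paste0("z_", names(z)))))
  dplyr::bind_cols(
    tibble::tibble(sample_id = sample_id), out,
    tibble::tibble(ff = ff, n_unique = n_unique, decision = d$decision,
                   positive_for = d$positive, no_call_reason = d$reason)
  )
}

#' Apply the calling rule to precomputed z-scores
#'
#' Convenience wrapper for scoring samples whose z-scores and fetal
#' fractions are already known (e.g. a published validation table):
#' applies the same strict `z > z_cutoff` / QC rule as [call_sample()].
#'
#' @param data tibble with a z-score column and optionally a fetal-fraction
#'   column (proportions or percent; values > 1 are treated as percent).
#' @param z_col,ff_col column names.
#' @param ff_floor,z_cutoff thresholds as in [call_sample()].
#' @return `data` with `decision` and `no_call_reason` columns added.
#' @export
call_from_scores <- function(data, z_col = "z", ff_col = NULL,
                             ff_floor = 0.04, z_cutoff = 3) {
  z <- data[[z_col]]
  ff <- if (is.null(ff_col)) rep(1, nrow(data)) else {
    v <- data[[ff_col]]
    ifelse(v > 1, v / 100, v)
  }
  res <- purrr::map2(z, ff, function(zi, fi) {
    decide_call(stats::setNames(zi, "tested"), fi, n_unique = NULL,
                min_reads = 0, ff_floor = ff_floor, z_cutoff = z_cutoff)
  })
  data$decision <- purrr::map_chr(res, "decision")
  data$no_call_reason <- purrr::map_chr(res, "reason")
  data
}

#' @rdname generics_reexports
#' @export
tidy.nips_reference <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
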