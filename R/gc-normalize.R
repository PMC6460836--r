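#' Count unique reads per genomic bin
#'
#' Assigns each fragment to the bin containing its start coordinate
#' (0-based, half-open bins) and tallies counts against the genome model's
#' bin tiling.
#'
#' @param records filtered fragment tibble.
#' @param genome a [genome_model()].
#' @param sample_id identifier carried into the bin table.
#' @return Bin-count tibble: `sample_id`, `chrom`, `bin_start`, `gc`,
#'   `width`, `raw_count`; `sum(raw_count)` equals `nrow(records)`.
#' @export
bin_counts <- function(records, genome, sample_id = "s1") {
  assert_fragments(records)
  bins <- genome$bins
  chroms <- genome$chromosomes
  ci <- match(records$chrom, chroms$chrom)
  if (anyNA(ci)) abort("record on a chromosome absent from the genome model")
  if (any(records$start < 0) ||
      any(records$start + records$length > chroms$length[ci])) {
    abort("malformed input: record beyond chromosome end")
  }
  nb_per_chrom <- ceiling(chroms$length / genome$bin_size)
  offset <- cumsum(c(0, nb_per_chrom[-length(nb_per_chrom)]))
  gbin <- offset[ci] + records$start %/% genome$bin_size + 1
  tibble::tibble(
    sample_id = sample_id,
    chrom = bins$chrom, bin_start = bins$bin_start,
    gc = bins$gc, width = bins$width,
    raw_count = as.double(tabulate(gbin, nbins = nrow(bins)))
  )
}

# step 1: per-sample LOESS of raw count vs GC; corrected = raw * median / fitted
gc_loess_step <- function(tab, span) {
  use <- !tab$masked
  fit <- stats::loess(raw_count ~ gc, data = tab[use, ], span = span,
                      degree = 2, family = "gaussian")
  fitted <- rep(NA_real_, nrow(tab))
  fitted[use] <- stats::predict(fit, tab$gc[use])
  bad <- use & (is.na(fitted) | fitted <= 0)
  tab$masked <- tab$masked | bad
  use <- !tab$masked
  med <- stats::median(tab$raw_count[use])
  corr <- rep(NA_real_, nrow(tab))
  corr[use] <- tab$raw_count[use] * med / fitted[use]
  corr[use] <- corr[use] * sum(tab$raw_count[use]) / sum(corr[use])
  tab$corrected <- corr
  tab
}

# step 3: quadratic GC regression of residual counts, floored at zero
gc_lm_step <- function(tab) {
  use <- !tab$masked
  fit <- stats::lm(corrected ~ gc + I(gc^2), data = tab[use, ])
  adj <- tab$corrected[use] - (stats::fitted(fit) - mean(stats::fitted(fit)))
  adj <- pmax(adj, 0)
  tab$corrected[use] <- adj * sum(tab$corrected[use]) / sum(adj)
  tab
}

#' Three-step GC correction for all samples of a sequencing run
#'
#' Step 1: per-sample LOESS regression of raw bin count on bin GC (span
#' 0.75, degree 2 -- the R defaults); each bin is rescaled by the ratio of
#' the genome-wide median count to its LOESS-fitted value. Step 2:
#' intrarun normalization -- each bin is divided by the median of its
#' step-1 value across the run's samples (requires at least
#' `min_run_samples` samples; skipped with a warning otherwise). Step 3:
#' linear-model regression of the step-2 counts on GC and GC^2; the
#' fitted GC component is subtracted and counts floored at zero. After
#' every step each sample's unmasked total is renormalized to its input
#' total, so chromosome ratios are comparable across steps.
#'
#' Bins are masked (corrected = NA, excluded from all ratio computations)
#' when they lie on a sex chromosome (dosage there depends on fetal sex
#' and fraction, not GC), when GC lies outside `gc_range`, when the bin
#' is a partial end-of-chromosome bin, when any sample's LOESS fit is
#' non-positive there, or when the run median is zero. The mask is
#' shared across the run so every sample's ratios use the same bin set.
#'
#' @param tables list of bin-count tibbles from [bin_counts()], one per
#'   run sample.
#' @param span LOESS span.
#' @param min_run_samples minimum run size for intrarun normalization.
#' @param gc_range GC interval outside which bins are masked.
#' @return List of corrected bin tables (columns `corrected`, `masked`
#'   added); attribute `intrarun_applied` on each.
#' @export
gc_correct_run <- function(tables, span = 0.75, min_run_samples = 8,
                           gc_range = c(0.2, 0.8)) {
  if (length(tables) == 0) abort("empty run")
  bin_size <- max(tables[[1]]$width)
  # sex-chromosome bins are excluded: their dosage depends on fetal sex and
  # fraction, so a GC-indexed smoother would treat them as local outliers
  mask0 <- tables[[1]]$gc < gc_range[1] | tables[[1]]$gc > gc_range[2] |
    tables[[1]]$width < bin_size | !(tables[[1]]$chrom %in% AUTOSOMES)

  step1 <- purrr::map(tables, function(tab) {
    tab$masked <- mask0
    gc_loess_step(tab, span)
  })
  # shared mask: a bin unusable in any sample is excluded run-wide
  mask <- Reduce(`|`, purrr::map(step1, "masked"))

  intrarun <- length(tables) >= min_run_samples
  if (!intrarun && length(tables) > 1) {
    warn(paste0("fewer than ", min_run_samples,
                " run samples; intrarun normalization skipped"))
  }
  if (intrarun) {
    mat <- do.call(cbind, purrr::map(step1, "corrected"))
    binmed <- apply(mat, 1, stats::median)
    mask <- mask | is.na(binmed) | binmed <= 0
  }

  purrr::map(step1, function(tab) {
    tab$masked <- mask
    tab$corrected[mask] <- NA_real_
    use <- !mask
    tot <- sum(tab$raw_count[use])
    if (intrarun) {
      tab$corrected[use] <- tab$corrected[use] / binmed[use]
      tab$corrected[use] <- tab$corrected[use] * tot /
        sum(tab$corrected[use])
    }
    tab <- gc_lm_step(tab)
    tab$corrected[use] <- tab$corrected[use] * tot /
      sum(tab$corrected[use])
    attr(tab, "intrarun_applied") <- intrarun
    tab
  })
}

#' @rdname gc_correct_run
#' @param table bin-count tibble for the test sample.
#' @param run_tables bin-count tibbles of the other samples of the run
#'   (the test sample itself is added to the run); `NULL` for a
#'   single-sample run (intrarun step skipped).
#' @return `gc_correct()`: the corrected bin table for `table`.
#' @export
gc_correct <- function(table, run_tables = NULL, span = 0.75,
                       min_run_samples = 8, gc_range = c(0.2, 0.8)) {
  run <- c(list(table), run_tables)
  gc_correct_run(run, span = span, min_run_samples = min_run_samples,
                 gc_range = gc_range)[[1]]
}
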