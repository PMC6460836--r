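#' Wilson score confidence interval
#'
#' The Wilson score interval for a binomial proportion; this is the
#' interval that reproduces published screening-performance CIs for small
#' numerators (where Wald fails and Clopper-Pearson over-covers).
#'
#' @param successes number of successes.
#' @param n number of trials (> 0).
#' @param conf confidence level.
#' @return Named vector `c(lo, hi)` of proportions.
#' @examples
#' round(100 * wilson_ci(5, 5), 2)   # 56.55, 100
#' @export
wilson_ci <- function(successes, n, conf = 0.95) {
  if (n <= 0) abort("n must be > 0")
  if (successes < 0 || successes > n) abort("successes must lie in [0, n]")
  z <- stats::qnorm((1 + conf) / 2)
  p <- successes / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  # exact endpoints at the boundary (guards floating-point residue)
  lo <- if (successes == 0) 0 else max(0, ctr - hw)
  hi <- if (successes == n) 1 else min(1, ctr + hw)
  c(lo = lo, hi = hi)
}

#' Confusion counts for a screening cohort
#'
#' Validated container for cohort-level screening counts. Test failures
#' (no-calls) are excluded from every metric denominator. `false_positive
#' = test_positive - true_positive` and `false_negative =
#' condition_positive - true_positive` are derived.
#'
#' @param n_total total samples.
#' @param n_fail test failures (no-calls).
#' @param true_positive confirmed positives among test positives.
#' @param test_positive samples called positive.
#' @param called_negative samples called negative.
#' @param condition_negative condition-negative samples in the metric
#'   denominators.
#' @param condition_positive condition-positive samples (default:
#'   `true_positive`, i.e. no missed positives).
#' @return One-row tibble of class `confusion_counts` including the
#'   derived `false_positive` and `false_negative`.
#' @export
confusion_counts <- function(n_total, n_fail, true_positive, test_positive,
                             called_negative, condition_negative,
                             condition_positive = true_positive) {
  cnt <- c(n_total, n_fail, true_positive, test_positive, called_negative,
           condition_negative, condition_positive)
  if (any(cnt < 0)) abort("counts must be >= 0")
  if (test_positive < true_positive) {
    abort("test_positive must be >= true_positive")
  }
  if (condition_positive < true_positive) {
    abort("condition_positive must be >= true_positive")
  }
  out <- tibble::tibble(
    n_total = n_total, n_fail = n_fail,
    true_positive = true_positive, test_positive = test_positive,
    called_negative = called_negative,
    condition_negative = condition_negative,
    condition_positive = condition_positive,
    false_positive = test_positive - true_positive,
    false_negative = condition_positive - true_positive
  )
  class(out) <- c("confusion_counts", class(out))
  out
}

metric_row <- function(metric, num, den, conf) {
  if (is.na(den) || den == 0) {
    return(tibble::tibble(metric = metric, numerator = NA_real_,
                          denominator = NA_real_, estimate_pct = NA_real_,
                          ci_lo_pct = NA_real_, ci_hi_pct = NA_real_))
  }
  ci <- wilson_ci(num, den, conf)
  tibble::tibble(
    metric = metric, numerator = num, denominator = den,
    estimate_pct = round_half_up(100 * num / den, 2),
    ci_lo_pct = round_half_up(100 * ci[["lo"]], 2),
    ci_hi_pct = round_half_up(100 * ci[["hi"]], 2)
  )
}

#' Screening performance metrics with Wilson CIs
#'
#' Sensitivity `TP / (TP + FN)`, specificity `TN_called /
#' condition_negative`, PPV `TP / test_positive`, NPV `TN_called /
#' called_negative` and the failure rate `n_fail / n_total`, where
#' `TN_called = called_negative - false_negative` (called negatives that
#' are truly negative). Each with a Wilson 95% CI; percentages rounded
#' half-up to two decimals. Metrics with a zero denominator are reported
#' as `NA`, never as 0.
#'
#' @param counts a [confusion_counts()] row.
#' @param conf confidence level.
#' @return Tibble with one row per metric: `metric`, `numerator`,
#'   `denominator`, `estimate_pct`, `ci_lo_pct`, `ci_hi_pct`.
#' @export
confusion_metrics <- function(counts, conf = 0.95) {
  stopifnot(inherits(counts, "confusion_counts"))
  tn_called <- counts$called_negative - counts$false_negative
  dplyr::bind_rows(
    metric_row("sensitivity", counts$true_positive,
               counts$true_positive + counts$false_negative, conf),
    metric_row("specificity", tn_called, counts$condition_negative, conf),
    metric_row("ppv", counts$true_positive, counts$test_positive, conf),
    metric_row("npv", tn_called, counts$called_negative, conf),
    metric_row("failure_rate", counts$n_fail, counts$n_total, conf)
  )
}

#' Compare two event rates
#'
#' Pearson chi-square test without continuity correction, or Fisher's
#' exact test (two-sided), on the 2x2 table of events/non-events; `"auto"`
#' uses Fisher when any expected cell count is below 5.
#'
#' @param a_events,a_n events and trials in group A.
#' @param b_events,b_n events and trials in group B.
#' @param method `"chi2"`, `"fisher"` or `"auto"`.
#' @return The p-value (scalar).
#' @export
compare_rates <- function(a_events, a_n, b_events, b_n,
                          method = c("auto", "chi2", "fisher")) {
  method <- match.arg(method)
  tab <- matrix(c(a_events, a_n - a_events, b_events, b_n - b_events),
                nrow = 2, byrow = TRUE)
  if (any(tab < 0)) abort("counts must be >= 0 with events <= n")
  if (sum(tab) == 0) abort("all-zero table")
  if (method == "auto") {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    method <- if (any(expected < 5)) "fisher" else "chi2"
  }
  if (method == "chi2") {
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  } else {
    stats::fisher.test(tab)$p.value
  }
}

#' Evaluate pipeline calls against simulation truth
#'
#' Tallies a cohort of call results against the generator's truth table.
#' No-calls count as test failures and are excluded from every metric
#' denominator. A test positive is a true positive only if the truth
#' trisomy chromosome is among the chromosomes called positive.
#'
#' @param calls tibble of [call_sample()] rows.
#' @param truths truth tibble (needs `sample_id`, `trisomy`).
#' @param conf confidence level for the metric CIs.
#' @return List with `counts` (a [confusion_counts()] row) and `metrics`
#'   (a [confusion_metrics()] table).
#' @export
evaluate_cohort <- function(calls, truths, conf = 0.95) {
  if (nrow(calls) == 0) abort("empty cohort")
  if (!setequal(calls$sample_id, truths$sample_id) ||
      nrow(calls) != nrow(truths)) {
    abort("sample ids of calls and truths do not match")
  }
  j <- dplyr::inner_join(calls, truths[, c("sample_id", "trisomy")],
                         by = "sample_id")
  ok <- j$decision != "no_call"
  jj <- j[ok, ]
  affected <- jj$trisomy != "none"
  pos <- jj$decision == "positive"
  hit <- pos & affected &
    purrr::map2_lgl(jj$trisomy, jj$positive_for, function(t, p) {
      t %in% strsplit(p, ",")[[1]]
    })
  counts <- confusion_counts(
    n_total = nrow(j), n_fail = sum(!ok),
    true_positive = sum(hit), test_positive = sum(pos),
    called_negative = sum(jj$decision == "negative"),
    condition_negative = sum(!affected),
    condition_positive = sum(affected)
  )
  list(counts = counts, metrics = confusion_metrics(counts, conf))
}
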