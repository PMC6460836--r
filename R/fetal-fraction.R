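#' chrY calibration constants
#'
#' The chrY-based fetal-fraction estimator needs two calibration constants:
#' `b_f`, the baseline chrY read fraction in a female-fetus pregnancy, and
#' `y_m`, the chrY read fraction of pure male tissue. Under the generator
#' model both are available in closed form from the genome bin weights and
#' the GC-bias curve (the maternal XX compartment emits no chrY reads, so
#' `b_f = 0`; `y_m` is chrY's weight share of the haploid-Y male genome).
#'
#' @param genome a [genome_model()].
#' @param gc_bias GC-bias curve in effect for the samples being analysed.
#' @return List with `b_f` and `y_m`.
#' @export
chry_calibration <- function(genome, gc_bias = gc_bias_curve()) {
  y_m <- expected_chrom_share(genome, "chrY", gc_bias, sex = "male")
  list(b_f = 0, y_m = y_m)
}

#' Fetal fraction from the chromosome-Y read share
#'
#' For a male-fetus pregnancy, `FF = (observed chrY fraction - b_f) /
#' (y_m - b_f)`, clamped to `[0, 1]`. Only valid for male fetuses.
#'
#' @param records fragment tibble (filtered; post-selection in enriched
#'   mode).
#' @param cal calibration list from [chry_calibration()].
#' @return Estimated fetal fraction (scalar in `[0, 1]`).
#' @export
ff_from_chry <- function(records, cal) {
  assert_fragments(records)
  if (cal$y_m <= cal$b_f) abort("invalid calibration: y_m must exceed b_f")
  if (nrow(records) == 0) abort("no reads")
  obs <- mean(records$chrom == "chrY")
  clamp((obs - cal$b_f) / (cal$y_m - cal$b_f), 0, 1)
}

#' Fragment-size feature ratios
#'
#' `r_a` is the read fraction in the short-fragment window (region A,
#' default \[130,140) bp, enriched in fetal DNA); `r_b` the fraction in the
#' long-fragment window (region B, default \[155,175) bp, enriched in
#' maternal DNA). Windows are half-open.
#'
#' @param records fragment tibble.
#' @param region_a,region_b length windows in bp.
#' @return One-row tibble with `r_a`, `r_b`, `n_reads`.
#' @export
size_ratios <- function(records, region_a = c(130, 140),
                        region_b = c(155, 175)) {
  assert_fragments(records)
  n <- nrow(records)
  if (n == 0) abort("no reads")
  tibble::tibble(
    r_a = sum(records$length >= region_a[1] &
                records$length < region_a[2]) / n,
    r_b = sum(records$length >= region_b[1] &
                records$length < region_b[2]) / n,
    n_reads = n
  )
}

#' Train the size-based fetal-fraction model
#'
#' Fits two univariate LOESS curves (span 0.75): fetal fraction against
#' `r_a` and against `r_b`, on a training cohort of male-fetus samples
#' whose fetal fractions come from the chrY estimator (the only truth
#' available in practice). Predictions outside the training range of a
#' feature are clamped to the range edge and flagged.
#'
#' @param training tibble with columns `r_a`, `r_b`, `ff`.
#' @param span LOESS span.
#' @param weights optional case weights.
#' @return Object of class `size_ff_model`.
#' @export
train_size_ff_model <- function(training, span = 0.75, weights = NULL) {
  need <- c("r_a", "r_b", "ff")
  if (!all(need %in% names(training))) {
    abort("training data must have columns r_a, r_b, ff")
  }
  if (nrow(training) < 10) abort("need at least 10 training samples")
  if (diff(range(training$r_a)) == 0 || diff(range(training$r_b)) == 0) {
    abort("degenerate feature range in training data")
  }
  if (is.null(weights)) weights <- rep(1, nrow(training))
  fit_a <- stats::loess(ff ~ r_a, data = training, span = span, degree = 2,
                        weights = weights,
                        control = stats::loess.control(surface = "direct"))
  fit_b <- stats::loess(ff ~ r_b, data = training, span = span, degree = 2,
                        weights = weights,
                        control = stats::loess.control(surface = "direct"))
  structure(
    list(
      fit_a = fit_a, fit_b = fit_b,
      range_a = range(training$r_a), range_b = range(training$r_b),
      n_train = nrow(training), span = span
    ),
    class = "size_ff_model"
  )
}

#' @export
print.size_ff_model <- function(x, ...) {
  cat("<size_ff_model> LOESS span", x$span, "trained on", x$n_train,
      "samples\n")
  cat("  r_a range:", signif(x$range_a, 4), "\n")
  cat("  r_b range:", signif(x$range_b, 4), "\n")
  invisible(x)
}

#' Consistency rule for the two size-feature predictions
#'
#' The exact arithmetic applied to the two feature-predicted fetal
#' fractions: the relative discrepancy `P_diff = (P_A - P_B) * 2 /
#' (P_A + P_B)` (signed, anti-symmetric under swap); the pair is
#' consistent (predictable) when `|P_diff| <= p_diff_max` (the ceiling
#' itself passes; default 0.40), in which case the combined estimate is
#' `P = (P_A + P_B) / 2`. `P_A + P_B = 0` is unpredictable by
#' construction.
#'
#' @param p_a,p_b feature-predicted fetal fractions (vectorised).
#' @param p_diff_max consistency ceiling on `|P_diff|`.
#' @return Tibble with `p_a`, `p_b`, `p_diff`, `predictable`, `ff` (NA
#'   when unpredictable).
#' @examples
#' ff_consistency(0.15, 0.10)  # P_diff exactly 0.4: still predictable
#' ff_consistency(0.20, 0.10)  # P_diff 2/3: unpredictable
#' @export
ff_consistency <- function(p_a, p_b, p_diff_max = 0.40) {
  denom <- p_a + p_b
  p_diff <- ifelse(denom > 0, (p_a - p_b) * 2 / denom, Inf)
  predictable <- is.finite(p_diff) & abs(p_diff) <= p_diff_max
  tibble::tibble(
    p_a = p_a, p_b = p_b, p_diff = p_diff, predictable = predictable,
    ff = ifelse(predictable, (p_a + p_b) / 2, NA_real_)
  )
}

# predict one feature curve with range clamping
predict_feature <- function(fit, rng, x) {
  clamped <- clamp(x, rng[1], rng[2])
  list(p = as.double(stats::predict(fit, data.frame(
    r_a = clamped, r_b = clamped)[, all.vars(fit$terms)[2], drop = FALSE])),
    clamped = clamped != x)
}

#' Size-based fetal-fraction estimate with consistency rule
#'
#' Predicts `P_A` from `r_a` and `P_B` from `r_b` via the trained curves.
#' The relative discrepancy `P_diff = (P_A - P_B) * 2 / (P_A + P_B)` is
#' reported signed (anti-symmetric under feature swap); the estimate is
#' deemed unpredictable when `|P_diff| > p_diff_max` (strict; default
#' 0.40, chosen to exceed 99% of normal samples), or when `P_A + P_B = 0`.
#' Otherwise the final estimate is `P = (P_A + P_B) / 2`.
#'
#' @param model a [train_size_ff_model()] fit.
#' @param r_a,r_b feature ratios from [size_ratios()] (vectorised).
#' @param p_diff_max consistency ceiling on `|P_diff|`.
#' @return Tibble with `p_a`, `p_b`, `p_diff`, `predictable`, `ff`
#'   (NA when unpredictable), `clamped`.
#' @export
estimate_ff_size <- function(model, r_a, r_b, p_diff_max = 0.40) {
  stopifnot(inherits(model, "size_ff_model"))
  a <- predict_feature(model$fit_a, model$range_a, r_a)
  b <- predict_feature(model$fit_b, model$range_b, r_b)
  out <- ff_consistency(pmax(a$p, 0), pmax(b$p, 0), p_diff_max)
  out$clamped <- a$clamped | b$clamped
  out
}

#' Build a size-model training table from a cohort
#'
#' Convenience wrapper: filters each sample's fragments, optionally applies
#' size selection (to train an enriched-protocol model), computes size
#' ratios and chrY-based fetal-fraction labels.
#'
#' @param cohort cohort tibble from [simulate_cohort()] (male-fetus
#'   samples).
#' @param cal chrY calibration from [chry_calibration()].
#' @param enriched apply [size_select()] before computing features.
#' @param cutoff size-selection cutoff when `enriched`.
#' @return Training tibble with `sample_id`, `r_a`, `r_b`, `ff`.
#' @export
size_ff_training <- function(cohort, cal, enriched = FALSE, cutoff = 160) {
  purrr::map2_dfr(cohort$sample_id, cohort$fragments, function(id, fr) {
    fr <- filter_reads(fr)
    if (enriched) fr <- size_select(fr, cutoff)
    dplyr::bind_cols(
      tibble::tibble(sample_id = id),
      size_ratios(fr),
      tibble::tibble(ff = ff_from_chry(fr, cal))
    )
  })
}

#' @rdname generics_reexports
#' @export
tidy.size_ff_model <- function(x, ...) {
  tibble::tibble(
    feature = c("r_a", "r_b"),
    region = c("short (region A)", "long (region B)"),
    range_lo = c(x$range_a[1], x$range_b[1]),
    range_hi = c(x$range_a[2], x$range_b[2]),
    residual_se = c(x$fit_a$s, x$fit_b$s)
  )
}

#' @rdname generics_reexports
#' @export
glance.size_ff_model <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train, span = x$span,
    sigma_a = x$fit_a$s, sigma_b = x$fit_b$s
  )
}
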