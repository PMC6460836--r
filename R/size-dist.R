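#' Fragment-size distributions for maternal and fetal cfDNA
#'
#' cfDNA fragment lengths peak at the chromatosome (~166 bp) and nucleosome
#' (~143 bp) protected sizes. Fetal (placental) cfDNA carries a reduced
#' 166 bp proportion and more mass below 150 bp than maternal cfDNA.
#' `size_distribution()` builds a discrete pmf on 50-250 bp as a mixture of
#' a long (chromatosome) Gaussian, a short (nucleosome) Gaussian, a
#' uniform sub-nucleosomal tail and a broad long-fragment shoulder (the
#' rising edge toward di-nucleosomal lengths); `maternal_size_dist()` and
#' `fetal_size_dist()` are the package defaults with the fetal mixture
#' shifted toward the short components.
#'
#' @param w_long,w_short,w_tail,w_shoulder mixture weights (must sum to 1).
#' @param mu_long,sd_long mean/sd of the chromatosome peak (bp).
#' @param mu_short,sd_short mean/sd of the nucleosome peak (bp).
#' @param tail range (bp) of the uniform short tail.
#' @param mu_shoulder,sd_shoulder mean/sd of the long-fragment shoulder.
#' @param support integer lengths the pmf is defined on.
#' @return A tibble of class `size_dist` with columns `length` and `prob`
#'   (summing to 1), parameters kept as attributes.
#' @examples
#' m <- maternal_size_dist()
#' f <- fetal_size_dist()
#' sum(f$prob[f$length < 150]) > sum(m$prob[m$length < 150])
#' @export
size_distribution <- function(w_long, w_short, w_tail, w_shoulder = 0,
                              mu_long = 166, sd_long = 4,
                              mu_short = 143, sd_short = 7,
                              tail = c(100, 140),
                              mu_shoulder = 190, sd_shoulder = 20,
                              support = 50:250) {
  w <- c(w_long, w_short, w_tail, w_shoulder)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    abort("mixture weights must be non-negative and sum to 1")
  }
  p <- w_long * stats::dnorm(support, mu_long, sd_long) +
    w_short * stats::dnorm(support, mu_short, sd_short) +
    w_tail * stats::dunif(support, tail[1], tail[2]) +
    w_shoulder * stats::dnorm(support, mu_shoulder, sd_shoulder)
  p <- p / sum(p)
  out <- tibble::tibble(length = as.integer(support), prob = p)
  attr(out, "params") <- list(
    w_long = w_long, w_short = w_short, w_tail = w_tail,
    w_shoulder = w_shoulder, mu_long = mu_long, sd_long = sd_long,
    mu_short = mu_short, sd_short = sd_short, tail = tail,
    mu_shoulder = mu_shoulder, sd_shoulder = sd_shoulder
  )
  class(out) <- c("size_dist", class(out))
  out
}

#' @rdname size_distribution
#' @export
maternal_size_dist <- function() {
  size_distribution(w_long = 0.84, w_short = 0.10, w_tail = 0.04,
                    w_shoulder = 0.02, mu_short = 143, sd_short = 7)
}

#' @rdname size_distribution
#' @export
fetal_size_dist <- function() {
  size_distribution(w_long = 0.42, w_short = 0.50, w_tail = 0.07,
                    w_shoulder = 0.01, mu_short = 141, sd_short = 10)
}

# pmf mass on [lo, hi) -- closed-form oracle helper used throughout
size_dist_mass <- function(dist, lo, hi) {
  sum(dist$prob[dist$length >= lo & dist$length < hi])
}

#' GC sampling-bias curve
#'
#' Unimodal quadratic bias in bin GC fraction, peaking at `peak` (default
#' 0.40): bins far from the peak are under-sampled. Amplitude 0 means no
#' bias. The curve is floored to stay positive.
#'
#' @param amplitude quadratic coefficient; 0 disables the bias.
#' @param peak GC fraction at which sampling efficiency is maximal.
#' @param floor minimum relative efficiency.
#' @return A function mapping GC fraction to a positive relative weight.
#' @export
gc_bias_curve <- function(amplitude = 6, peak = 0.40, floor = 0.05) {
  if (amplitude < 0) abort("amplitude must be >= 0")
  function(gc) pmax(floor, 1 - amplitude * (gc - peak)^2)
}

#' Bead size-selection retention curve
#'
#' Stochastic analogue of magnetic-bead size selection targeting fragments
#' below ~160 bp: each fragment is retained with a probability that
#' decreases logistically in fragment length, with midpoint 160 bp. The
#' three presets mimic increasing bead ratios; 1.5x is the steepest (closest
#' to a hard cutoff).
#'
#' @param preset bead-ratio preset: `"1.5x"`, `"1.3x"` or `"1.2x"`.
#' @param midpoint length (bp) at which retention is 0.5.
#' @param steepness logistic scale (bp); overrides the preset when given.
#' @return A function mapping fragment length to retention probability.
#' @export
bead_retention_curve <- function(preset = c("1.5x", "1.3x", "1.2x"),
                                 midpoint = 160, steepness = NULL) {
  preset <- match.arg(preset)
  if (is.null(steepness)) {
    steepness <- switch(preset, "1.5x" = 4, "1.3x" = 8, "1.2x" = 12)
  }
  function(length) 1 / (1 + exp((length - midpoint) / steepness))
}
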