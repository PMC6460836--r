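test_that("Wilson intervals mirror under success/failure reflection", {
  for (case in list(c(3, 10), c(0, 5), c(17, 20), c(250, 1000))) {
    ci <- wilson_ci(case[1], case[2])
    ref <- wilson_ci(case[2] - case[1], case[2])
    expect_equal(ci[["lo"]], 1 - ref[["hi"]], tolerance = 1e-12)
    expect_equal(ci[["hi"]], 1 - ref[["lo"]], tolerance = 1e-12)
    expect_true(ci[["lo"]] <= case[1] / case[2] &&
                  case[1] / case[2] <= ci[["hi"]])
  }
  expect_error(wilson_ci(1, 0), "> 0")
  expect_error(wilson_ci(6, 5), "\\[0, n\\]")
})

test_that("small-numerator Wilson bounds match published screening CIs", {
  expect_equal(round(100 * wilson_ci(5, 5), 2),
               c(lo = 56.55, hi = 100))
  expect_equal(round(100 * wilson_ci(0, 5), 2),
               c(lo = 0, hi = 43.45))
  expect_equal(round(100 * wilson_ci(1394, 1397), 2),
               c(lo = 99.37, hi = 99.93))
})

test_that("confusion counts validate and derive FP/FN", {
  cc <- confusion_counts(n_total = 100, n_fail = 2, true_positive = 4,
                         test_positive = 6, called_negative = 92,
                         condition_negative = 94, condition_positive = 4)
  expect_equal(cc$false_positive, 2)
  expect_equal(cc$false_negative, 0)
  expect_error(confusion_counts(10, 0, 5, 4, 1, 1), "test_positive")
  expect_error(confusion_counts(10, 0, 5, 6, 1, 1, condition_positive = 4),
               "condition_positive")
})

test_that("zero-denominator metrics are reported as missing, not zero", {
  cc <- confusion_counts(n_total = 10, n_fail = 0, true_positive = 0,
                         test_positive = 0, called_negative = 10,
                         condition_negative = 10)
  m <- confusion_metrics(cc)
  expect_true(is.na(m$estimate_pct[m$metric == "sensitivity"]))
  expect_true(is.na(m$estimate_pct[m$metric == "ppv"]))
  expect_equal(m$estimate_pct[m$metric == "npv"], 100)
})

test_that("rate comparison: chi-square without correction, Fisher, and auto dispatch", {
  expect_equal(compare_rates(5, 100, 5, 100, method = "chi2"), 1.0)
  expect_equal(compare_rates(1, 2, 1, 2, method = "fisher"), 1.0)
  expect_error(compare_rates(0, 0, 0, 0), "zero")

  # chi-square p equals the closed-form tail probability of the Pearson
  # statistic (quadrature oracle via numeric integration of the density)
  a <- 10; b <- 1; n <- 1404
  tab <- matrix(c(a, n - a, b, n - b), 2, byrow = TRUE)
  num <- (sum(tab) * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2)
  den <- prod(rowSums(tab)) * prod(colSums(tab))
  x2 <- num / den
  p_oracle <- stats::integrate(function(u) stats::dchisq(u, df = 1),
                               lower = x2, upper = Inf)$value
  expect_equal(compare_rates(a, n, b, n, method = "chi2"), p_oracle,
               tolerance = 1e-4)

  # auto picks Fisher when an expected cell drops below 5
  small <- compare_rates(1, 10, 0, 10, method = "auto")
  expect_equal(small, stats::fisher.test(matrix(c(1, 9, 0, 10), 2,
                                                byrow = TRUE))$p.value)
  big <- compare_rates(50, 100, 30, 100, method = "auto")
  expect_equal(big, suppressWarnings(
    stats::chisq.test(matrix(c(50, 50, 30, 70), 2, byrow = TRUE),
                      correct = FALSE)$p.value))
})

test_that("cohort evaluation tallies calls against truth and excludes no-calls", {
  calls <- tibble::tibble(
    sample_id = sprintf("s%d", 1:6),
    decision = c("positive", "negative", "negative", "no_call", "positive",
                 "negative"),
    positive_for = c("chr21", "", "", "", "chr18", "")
  )
  truths <- tibble::tibble(
    sample_id = sprintf("s%d", 1:6),
    trisomy = c("chr21", "none", "none", "none", "chr18", "none")
  )
  ev <- evaluate_cohort(calls, truths)
  expect_equal(ev$counts$n_fail, 1)
  expect_equal(ev$counts$true_positive, 2)
  expect_equal(ev$counts$condition_negative, 3)
  m <- ev$metrics
  expect_equal(m$estimate_pct[m$metric == "ppv"], 100)
  expect_equal(m$estimate_pct[m$metric == "npv"], 100)
  expect_equal(m$estimate_pct[m$metric == "sensitivity"], 100)

  expect_error(evaluate_cohort(calls[0, ], truths[0, ]), "empty")
  expect_error(evaluate_cohort(calls, truths[1:5, ]), "ids")
})

test_that("percentages round half-up for reporting", {
  expect_equal(cffenrich:::round_half_up(0.125, 2), 0.13)
  expect_equal(cffenrich:::round_half_up(62.495, 2), 62.5)
  expect_equal(cffenrich:::round_half_up(-0.125, 2), -0.13)
})
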