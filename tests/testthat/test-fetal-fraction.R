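gm <- genome_model()

test_that("chrY estimator maps the calibration endpoints to 0 and 1", {
  cal <- chry_calibration(gm)
  no_y <- frag_tbl(rep("chr1", 100), 1:100, rep(150, 100))
  expect_equal(ff_from_chry(no_y, cal), 0)
  all_y <- frag_tbl(rep("chrY", 100), 1:100, rep(150, 100))
  expect_equal(ff_from_chry(all_y, cal), 1)
  expect_error(ff_from_chry(no_y, list(b_f = 0.5, y_m = 0.4)), "calibration")
})

test_that("chrY estimator recovers generator truth across a cohort", {
  truth_ff <- 0.12
  cal <- chry_calibration(gm)
  est <- vapply(1:50, function(i) {
    s <- filter_reads(simulate_sample(
      gm, sample_truth(truth_ff, "male", n_fragments = 5e4, seed = 700 + i)
    ))
    ff_from_chry(s, cal)
  }, double(1))
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - truth_ff), 3 * se)
})

test_that("size ratios use half-open windows", {
  all_a <- frag_tbl(rep("chr1", 4), 1:4, rep(135, 4))
  sr <- size_ratios(all_a)
  expect_equal(sr$r_a, 1)
  expect_equal(sr$r_b, 0)

  edges <- frag_tbl(rep("chr1", 4), 1:4, c(130, 140, 155, 175))
  sr2 <- size_ratios(edges)
  expect_equal(sr2$r_a, 0.25)  # 140 excluded
  expect_equal(sr2$r_b, 0.25)  # 175 excluded
  expect_error(size_ratios(all_a[0, ]), "no reads")
})

test_that("higher fetal fraction raises r_a and lowers r_b", {
  res <- purrr::map_dfr(1:10, function(i) {
    lo <- filter_reads(simulate_sample(
      gm, sample_truth(0.05, "male", n_fragments = 2e4, seed = 800 + i)))
    hi <- filter_reads(simulate_sample(
      gm, sample_truth(0.25, "male", n_fragments = 2e4, seed = 900 + i)))
    tibble::tibble(
      d_a = size_ratios(hi)$r_a - size_ratios(lo)$r_a,
      d_b = size_ratios(hi)$r_b - size_ratios(lo)$r_b
    )
  })
  expect_true(all(res$d_a > 0))
  expect_true(all(res$d_b < 0))
})

test_that("the size model reproduces a noiseless linear relation within 1%", {
  r_a <- seq(0.03, 0.17, length.out = 40)
  r_b <- seq(0.80, 0.40, length.out = 40)
  ff <- 0.02 + 2 * r_a            # exactly linear in both features
  training <- tibble::tibble(r_a = r_a, r_b = r_b, ff = ff)
  model <- train_size_ff_model(training)
  inside <- seq(0.05, 0.15, length.out = 11)
  pred <- estimate_ff_size(model, inside, r_b = 0.80 - (inside - 0.03) /
                             (0.14 / 0.4))
  expected <- 0.02 + 2 * inside
  expect_lt(max(abs(pred$p_a - expected) / expected), 0.01)
  expect_lt(max(abs(pred$ff - expected) / expected), 0.01)
})

test_that("duplicated training rows equal a weights-2 fit", {
  set.seed(5)
  training <- tibble::tibble(
    r_a = runif(30, 0.03, 0.17),
    r_b = runif(30, 0.4, 0.8),
    ff = runif(30, 0.03, 0.3)
  )
  doubled <- dplyr::bind_rows(training, training)
  m_dup <- train_size_ff_model(doubled)
  m_w <- train_size_ff_model(training, weights = rep(2, 30))
  x <- seq(0.05, 0.15, length.out = 7)
  y <- seq(0.45, 0.75, length.out = 7)
  # near-equivalence: the smoother's neighbourhoods are quantile-based, so
  # replication can shift a local window by one point
  expect_equal(estimate_ff_size(m_dup, x, y)$p_a,
               estimate_ff_size(m_w, x, y)$p_a, tolerance = 0.1)
  expect_equal(estimate_ff_size(m_dup, x, y)$p_b,
               estimate_ff_size(m_w, x, y)$p_b, tolerance = 0.1)
})

test_that("training rejects degenerate inputs", {
  flat <- tibble::tibble(r_a = rep(0.1, 20), r_b = seq(0.4, 0.8,
                                                       length.out = 20),
                         ff = seq(0.05, 0.2, length.out = 20))
  expect_error(train_size_ff_model(flat), "degenerate")
  expect_error(train_size_ff_model(flat[1:5, ]), "at least 10")
  expect_error(train_size_ff_model(tibble::tibble(x = 1)), "columns")
})

test_that("the consistency rule applies the published arithmetic with a strict ceiling", {
  # boundary: P_diff exactly 0.40 stays predictable
  at_boundary <- ff_consistency(0.15, 0.10)
  expect_equal(at_boundary$p_diff, 0.4)
  expect_true(at_boundary$predictable)
  expect_equal(at_boundary$ff, 0.125)

  beyond <- ff_consistency(0.20, 0.10)
  expect_equal(beyond$p_diff, 2 / 3)
  expect_false(beyond$predictable)
  expect_true(is.na(beyond$ff))

  same <- ff_consistency(0.10, 0.10)
  expect_equal(same$p_diff, 0)
  expect_equal(same$ff, 0.10)

  zero <- ff_consistency(0, 0)
  expect_false(zero$predictable)
})

test_that("P_diff is anti-symmetric and the flag uses its magnitude", {
  set.seed(7)
  a <- runif(50, 0.01, 0.3)
  b <- runif(50, 0.01, 0.3)
  expect_equal(ff_consistency(a, b)$p_diff, -ff_consistency(b, a)$p_diff)
  expect_equal(ff_consistency(a, b)$predictable,
               ff_consistency(b, a)$predictable)
  # a rule on the signed value would never flag p_b >> p_a; ours does
  expect_false(ff_consistency(0.02, 0.20)$predictable)
})

test_that("model predictions outside the training range are clamped and flagged", {
  training <- tibble::tibble(
    r_a = seq(0.05, 0.15, length.out = 30),
    r_b = seq(0.75, 0.45, length.out = 30),
    ff = seq(0.04, 0.28, length.out = 30)
  )
  model <- train_size_ff_model(training)
  out <- estimate_ff_size(model, 0.30, 0.60)
  expect_true(out$clamped)
  inside <- estimate_ff_size(model, 0.10, 0.60)
  expect_false(inside$clamped)
})
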