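test_that("chromosome ratio is the unmasked corrected-count share of autosomes", {
  # chr21 carries 10% of the counts of a uniform toy table
  tab <- ratio_table(chr21_count = 100, autosome_count = 900)
  expect_equal(chromosome_ratio(tab, "chr21"), 0.10)

  single <- ratio_table(chr21_count = 500, autosome_count = 0, n_bins = 0)
  expect_equal(chromosome_ratio(single, "chr21"), 1.0)

  masked <- ratio_table(100, 900)
  masked$masked[masked$chrom == "chr21"] <- TRUE
  expect_error(chromosome_ratio(masked, "chr21"), "unmasked")
})

test_that("trisomic dosage shifts the ratio by the (1 + f/2) factor", {
  gm <- genome_model()
  ff <- 0.12
  reps <- 12
  ratios <- vapply(seq_len(reps), function(i) {
    tri <- filter_reads(simulate_sample(
      gm, sample_truth(ff, "male", trisomy = "chr21", n_fragments = 5e4,
                       seed = 300 + i),
      gc_bias = gc_bias_curve(amplitude = 0)
    ))
    eu <- filter_reads(simulate_sample(
      gm, sample_truth(ff, "male", trisomy = "none", n_fragments = 5e4,
                       seed = 600 + i),
      gc_bias = gc_bias_curve(amplitude = 0)
    ))
    chromosome_ratio(bin_counts(tri, gm), "chr21") /
      chromosome_ratio(bin_counts(eu, gm), "chr21")
  }, double(1))
  se <- stats::sd(ratios) / sqrt(reps)
  expect_lt(abs(mean(ratios) - (1 + ff / 2)), 3 * se + 0.005)
})

test_that("reference statistics use the n-1 sample SD and reject degeneracy", {
  # chr21 ratios exactly 0.009 and 0.011 (denominator includes chr21)
  t1 <- ratio_table(9, 991)
  t2 <- ratio_table(11, 989)
  ref <- build_reference(list(t1, t2), chroms = "chr21", min_samples = 2)
  expect_equal(ref$mu, 0.010, tolerance = 1e-12)
  expect_equal(ref$sd, 0.0014142, tolerance = 1e-4)
  expect_equal(ref$sd, stats::sd(c(0.009, 0.011)))
  expect_error(build_reference(list(t1, t1), chroms = "chr21",
                               min_samples = 2), "degenerate")
  expect_error(build_reference(list(t1), chroms = "chr21"), "at least 20")
})

test_that("z-scores are linear in the ratio and the cutoff is strict", {
  ref <- structure(
    tibble::tibble(chrom = "chr21", mu = 0.015, sd = 0.0005, n = 30),
    class = c("nips_reference", "tbl_df", "tbl", "data.frame")
  )
  expect_equal(z_score(0.015, ref, "chr21"), 0)
  expect_equal(z_score(0.015 + 3 * 0.0005, ref, "chr21"), 3)
  expect_error(z_score(0.015, ref, "chr18"), "not present")
  # z exactly 3 is NOT positive: cutoff is strict
  calls <- call_from_scores(tibble::tibble(z = c(3, 3.0001), ff = c(10, 10)),
                            ff_col = "ff")
  expect_equal(calls$decision, c("negative", "positive"))
  # monotonicity in ratio
  zs <- vapply(seq(0.014, 0.018, by = 0.0005), z_score, double(1),
               reference = ref, chrom = "chr21")
  expect_true(all(diff(zs) > 0))
})

test_that("the QC gates fire in order: reads, unpredictable FF, FF floor", {
  low_ff <- call_from_scores(tibble::tibble(z = 10, ff = 3.9), ff_col = "ff")
  expect_equal(low_ff$decision, "no_call")
  expect_equal(low_ff$no_call_reason, "low_ff")
  at_floor <- call_from_scores(tibble::tibble(z = 10, ff = 4.0), ff_col = "ff")
  expect_equal(at_floor$decision, "positive")

  gm <- genome_model()
  ref <- structure(
    tibble::tibble(chrom = c("chr13", "chr18", "chr21"),
                   mu = c(0.037, 0.023, 0.015), sd = rep(5e-4, 3), n = 30),
    class = c("nips_reference", "tbl_df", "tbl", "data.frame")
  )
  tab <- ratio_table(15, 985)
  tab$chrom[1:2] <- c("chr13", "chr18")
  res <- call_sample(tab, ref, ff = 0.1, n_unique = 10,
                     min_reads = scaled_min_reads(gm))
  expect_equal(res$decision, "no_call")
  expect_equal(res$no_call_reason, "low_reads")
  res2 <- call_sample(tab, ref, ff = NA_real_, n_unique = 1e6,
                      min_reads = 100, ff_predictable = FALSE)
  expect_equal(res2$no_call_reason, "ff_unpredictable")
})

test_that("euploid z-scores against an independent reference are standard-normal-like", {
  gm <- genome_model()
  flat <- gc_bias_curve(amplitude = 0)
  make_tabs <- function(seeds) {
    lapply(seeds, function(sd) {
      s <- filter_reads(simulate_sample(
        gm, sample_truth(0.1, "male", n_fragments = 5e4, seed = sd),
        gc_bias = flat
      ))
      bin_counts(s, gm)
    })
  }
  ref <- build_reference(gc_correct_run(make_tabs(1000 + 1:25)),
                         min_samples = 20)
  test_tabs <- gc_correct_run(make_tabs(2000 + 1:40))
  z <- vapply(test_tabs, function(t) {
    z_score(chromosome_ratio(t, "chr21"), ref, "chr21")
  }, double(1))
  expect_gt(mean(abs(z) < 3), 0.9)
  expect_lt(abs(mean(z)), 1)
})
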