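gm_small <- genome_model()

test_that("zero fetal fraction yields no fetal fragments", {
  s <- simulate_sample(gm_small, sample_truth(0, "male", n_fragments = 5000))
  expect_equal(sum(s$origin == "fetal"), 0)
})

test_that("fetal fragment share matches the binomial draw", {
  n <- 1e5
  s <- simulate_sample(gm_small,
                       sample_truth(0.10, "male", n_fragments = n, seed = 1))
  primary <- s[!s$is_duplicate, ]
  se <- sqrt(0.10 * 0.90 / n)
  expect_lt(abs(mean(primary$origin == "fetal") - 0.10), 3 * se)
})

test_that("trisomy gives the affected chromosome 1.5x fetal weight", {
  s <- simulate_sample(
    gm_small,
    sample_truth(0.5, "male", trisomy = "chr21", n_fragments = 2e5, seed = 4)
  )
  fet <- s[s$origin == "fetal" & !s$is_duplicate, ]
  p_tri <- expected_chrom_share(gm_small, "chr21", sex = "male",
                                trisomy = "chr21")
  p_dis <- expected_chrom_share(gm_small, "chr21", sex = "male")
  obs <- mean(fet$chrom == "chr21")
  se <- sqrt(p_tri * (1 - p_tri) / nrow(fet))
  expect_lt(abs(obs - p_tri), 3 * se)
  # and the trisomic expectation really is ~1.5x the disomic one
  expect_gt(obs / p_dis, 1.4)
})

test_that("female fetuses emit no fetal chrY fragments", {
  s <- simulate_sample(gm_small,
                       sample_truth(0.2, "female", n_fragments = 5e4, seed = 2))
  expect_equal(sum(s$chrom == "chrY"), 0)
})

test_that("fragments respect chromosome bounds and length bounds", {
  s <- simulate_sample(gm_small, sample_truth(0.1, "male", n_fragments = 5e4,
                                              seed = 9))
  len <- gm_small$chromosomes$length[match(s$chrom,
                                           gm_small$chromosomes$chrom)]
  expect_true(all(s$start >= 0))
  expect_true(all(s$start + s$length <= len))
  expect_true(all(s$length >= 50 & s$length <= 250))
})

test_that("truth and generation parameters are validated", {
  expect_error(sample_truth(0.6), "\\[0, 0.5\\]")
  expect_error(sample_truth(0.1, trisomy = "chr7"), "trisomy")
  expect_error(sample_truth(0.1, n_fragments = 0), "> 0")
})

test_that("cohorts are reproducible under a fixed seed and empty cohorts are valid", {
  a <- simulate_cohort(gm_small, 4, seed = 7, n_fragments = 2000)
  b <- simulate_cohort(gm_small, 4, seed = 7, n_fragments = 2000)
  expect_identical(a, b)
  e <- simulate_cohort(gm_small, 0)
  expect_equal(nrow(e), 0)
})

test_that("trisomy prevalence draws fall in the binomial central interval", {
  co <- simulate_cohort(gm_small, 200, seed = 3, n_fragments = 100,
                        prevalence = 0.5)
  k <- sum(co$trisomy != "none")
  expect_gte(k, qbinom(0.005, 200, 0.5))
  expect_lte(k, qbinom(0.995, 200, 0.5))
})

test_that("bead enrichment keeps a subset and step retention equals the hard cutoff", {
  s <- simulate_sample(gm_small, sample_truth(0.1, "male", n_fragments = 2e4,
                                              seed = 5))
  keep_all <- simulate_bead_enrichment(s, retention = function(l) rep(1, length(l)))
  expect_identical(keep_all, s)
  step <- simulate_bead_enrichment(s, retention = function(l) as.numeric(l < 160))
  expect_identical(step, size_select(s, 160))
  soft <- simulate_bead_enrichment(s, bead_retention_curve("1.5x"), seed = 8)
  expect_lte(nrow(soft), nrow(s))
  key <- function(x) paste(x$chrom, x$start, x$length)
  expect_true(all(key(soft) %in% key(s)))
  expect_error(
    simulate_bead_enrichment(s, retention = function(l) rep(1.5, length(l))),
    "\\[0, 1\\]"
  )
})

test_that("bead enrichment raises the fetal fraction of a male sample", {
  s <- filter_reads(simulate_sample(
    gm_small, sample_truth(0.10, "male", n_fragments = 1e5, seed = 6)
  ))
  cal <- chry_calibration(gm_small)
  pre <- ff_from_chry(s, cal)
  post <- ff_from_chry(
    simulate_bead_enrichment(s, bead_retention_curve("1.5x"), seed = 7), cal
  )
  expect_gt(post, pre)
  expect_gt(post / pre, 1.5)
  expect_lt(post / pre, 4)
})

test_that("fragment tables round-trip through the TSV dialect", {
  s <- simulate_sample(gm_small, sample_truth(0.1, "male", n_fragments = 2000,
                                              seed = 10))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fragments(s, path)
  back <- read_fragments(path)
  expect_equal(back$chrom, s$chrom)
  expect_equal(back$start, s$start)
  expect_equal(back$length, s$length)
  expect_equal(back$is_duplicate, s$is_duplicate)
  expect_equal(back$origin, s$origin)
})
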