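#' Ground truth for one simulated sample
#'
#' @param fetal_fraction fetal fraction in `[0, 0.5]`.
#' @param fetal_sex `"male"` or `"female"`.
#' @param trisomy `"chr13"`, `"chr18"`, `"chr21"` or `"none"`.
#' @param n_fragments number of primary fragments to draw (> 0).
#' @param seed integer RNG seed for the sample.
#' @param sample_id identifier.
#' @return One-row tibble with the truth fields.
#' @export
sample_truth <- function(fetal_fraction, fetal_sex = c("male", "female"),
                         trisomy = "none", n_fragments = 2e5, seed = 1,
                         sample_id = "s1") {
  fetal_sex <- match.arg(fetal_sex)
  if (fetal_fraction < 0 || fetal_fraction > 0.5) {
    abort("fetal_fraction must lie in [0, 0.5]")
  }
  if (!trisomy %in% c("chr13", "chr18", "chr21", "none")) {
    abort("trisomy must be one of chr13, chr18, chr21, none")
  }
  if (n_fragments <= 0) abort("n_fragments must be > 0")
  tibble::tibble(
    sample_id = sample_id,
    fetal_fraction = fetal_fraction,
    fetal_sex = fetal_sex,
    trisomy = trisomy,
    n_fragments = as.double(n_fragments),
    seed = as.integer(seed)
  )
}

# draw fragments for one tissue (origin) given bin weights and a size pmf
draw_tissue_fragments <- function(n, genome, weights, dist) {
  bins <- genome$bins
  if (n == 0) {
    return(tibble::tibble(
      chrom = character(), start = double(), length = integer()
    ))
  }
  idx <- sample.int(nrow(bins), n, replace = TRUE, prob = weights)
  width <- bins$width[idx]
  start <- bins$bin_start[idx] + floor(stats::runif(n) * width)
  len <- sample(dist$length, n, replace = TRUE, prob = dist$prob)
  chrom_len <- genome$chromosomes$length[match(bins$chrom[idx],
                                               genome$chromosomes$chrom)]
  start <- pmax(0, pmin(start, chrom_len - len))
  tibble::tibble(chrom = bins$chrom[idx], start = start, length = len)
}

#' Simulate one maternal-plasma cfDNA sample
#'
#' Draws `n_fragments` aligned fragment records. Each fragment is fetal with
#' probability `fetal_fraction`; its genomic bin is drawn proportional to
#' bin width x copy number x GC bias, its length from the matching
#' maternal/fetal size distribution, and its start uniformly within the
#' bin. Male fetuses contribute chrY fragments in proportion to chrY's
#' share of the (haploid-Y) fetal genome; a trisomic chromosome carries
#' 1.5x weight in the fetal genome. On top of the counting noise, each
#' sample carries a multiplicative per-chromosome representation factor
#' (log-normal with coefficient of variation `bio_cv`, shared by both
#' tissues) emulating the between-sample biological/technical
#' variability that dominates the spread of chromosome ratios in deep
#' sequencing. A configurable fraction of records is then re-emitted as
#' flagged duplicates, and a fraction flagged multi-mapped. The `origin`
#' column is a truth channel for validation only; no analysis function
#' reads it.
#'
#' @param genome a [genome_model()].
#' @param truth one-row truth tibble from [sample_truth()].
#' @param gc_bias GC-bias curve from [gc_bias_curve()].
#' @param maternal_dist,fetal_dist size distributions ([size_distribution()]).
#' @param dup_rate fraction of records re-emitted as flagged duplicates.
#' @param multimap_rate fraction of records flagged as non-unique mappers.
#' @param bio_cv coefficient of variation of the per-sample
#'   per-chromosome representation factor (0 disables it).
#' @return Fragment tibble: `chrom`, `start` (0-based), `length`,
#'   `is_duplicate`, `is_unique_mapping`, `origin`.
#' @examples
#' gm <- genome_model()
#' fr <- simulate_sample(gm, sample_truth(0.1, "male", n_fragments = 1e4))
#' mean(fr$origin == "fetal")
#' @export
simulate_sample <- function(genome, truth,
                            gc_bias = gc_bias_curve(),
                            maternal_dist = maternal_size_dist(),
                            fetal_dist = fetal_size_dist(),
                            dup_rate = 0.02, multimap_rate = 0.01,
                            bio_cv = 0.01) {
  stopifnot(inherits(genome, "genome_model"))
  if (truth$n_fragments <= 0) abort("n_fragments must be > 0")
  withr::with_seed(truth$seed, {
    n <- truth$n_fragments
    n_fetal <- stats::rbinom(1, n, truth$fetal_fraction)
    n_mat <- n - n_fetal

    # sample-level chromosomal representation noise, common to both tissues
    chrom_f <- exp(stats::rnorm(nrow(genome$chromosomes), 0, bio_cv))
    bin_f <- chrom_f[match(genome$bins$chrom, genome$chromosomes$chrom)]

    w_mat <- bin_f * genome_bin_weights(genome, gc_bias, sex = "female",
                                        trisomy = "none")
    w_fet <- bin_f * genome_bin_weights(genome, gc_bias,
                                        sex = truth$fetal_sex,
                                        trisomy = truth$trisomy)
    mat <- draw_tissue_fragments(n_mat, genome, w_mat, maternal_dist)
    fet <- draw_tissue_fragments(n_fetal, genome, w_fet, fetal_dist)
    if (truth$fetal_sex == "female" && any(fet$chrom == "chrY")) {
      abort("internal error: chrY fetal fragments emitted for a female fetus")
    }
    rec <- dplyr::bind_rows(
      dplyr::mutate(mat, origin = "maternal"),
      dplyr::mutate(fet, origin = "fetal")
    )
    rec$is_duplicate <- FALSE
    rec$is_unique_mapping <- stats::runif(nrow(rec)) >= multimap_rate

    n_dup <- round(dup_rate * nrow(rec))
    if (n_dup > 0) {
      dup <- rec[sample.int(nrow(rec), n_dup, replace = TRUE), ]
      dup$is_duplicate <- TRUE
      rec <- dplyr::bind_rows(rec, dup)
    }
    rec
  })
}

#' Simulate a cohort of cfDNA samples
#'
#' Fetal fractions are drawn from a truncated normal (defaults mirror a
#' routine screening population: mean 11.3%, sd 4.2%, truncated to
#' `[0.03, 0.30]`), fetal sex from `p_male`, and trisomy status from
#' `prevalence` (split across the chromosomes in `trisomy_chroms`).
#' Per-sample seeds are derived deterministically from `seed`, so the
#' cohort is reproducible.
#'
#' @param genome a [genome_model()].
#' @param n_samples number of samples.
#' @param seed master integer seed.
#' @param n_fragments fragments per sample.
#' @param ff_mean,ff_sd,ff_range fetal-fraction distribution parameters.
#' @param prevalence probability a sample is trisomic.
#' @param trisomy_chroms chromosomes among which trisomies are split.
#' @param p_male probability of a male fetus.
#' @param fixed_ff optional fixed fetal fraction (overrides the ff draw).
#' @param ... passed on to [simulate_sample()].
#' @return A tibble with one row per sample: the truth columns plus a
#'   `fragments` list-column of fragment tibbles.
#' @export
simulate_cohort <- function(genome, n_samples, seed = 1, n_fragments = 2e5,
                            ff_mean = 0.113, ff_sd = 0.042,
                            ff_range = c(0.03, 0.30),
                            prevalence = 0, trisomy_chroms = "chr21",
                            p_male = 0.5, fixed_ff = NULL, ...) {
  if (n_samples == 0) {
    t0 <- sample_truth(0.1)[0, ]
    t0$fragments <- list()
    return(t0)
  }
  truths <- withr::with_seed(seed, {
    ff <- if (is.null(fixed_ff)) {
      clamp(stats::rnorm(n_samples, ff_mean, ff_sd), ff_range[1], ff_range[2])
    } else rep(fixed_ff, n_samples)
    sex <- ifelse(stats::runif(n_samples) < p_male, "male", "female")
    tri <- ifelse(stats::runif(n_samples) < prevalence,
                  sample(trisomy_chroms, n_samples, replace = TRUE), "none")
    tibble::tibble(
      sample_id = sprintf("s%03d", seq_len(n_samples)),
      fetal_fraction = ff, fetal_sex = sex, trisomy = tri,
      n_fragments = as.double(n_fragments),
      seed = vapply(seq_len(n_samples), function(i) derive_seed(seed, i),
                    integer(1))
    )
  })
  truths$fragments <- purrr::map(seq_len(n_samples), function(i) {
    simulate_sample(genome, truths[i, ], ...)
  })
  truths
}

#' Stochastic bead size-selection of a fragment set
#'
#' Each record is kept independently with probability `retention(length)`.
#' With the default decreasing logistic curves this emulates magnetic-bead
#' enrichment of sub-160 bp fragments; a step function at 160 bp reproduces
#' [size_select()] exactly.
#'
#' @param records fragment tibble.
#' @param retention function mapping length to retention probability in
#'   `[0, 1]` (see [bead_retention_curve()]).
#' @param seed integer seed.
#' @return The retained subset of `records`.
#' @export
simulate_bead_enrichment <- function(records, retention = bead_retention_curve(),
                                     seed = 1) {
  assert_fragments(records)
  p <- retention(records$length)
  if (any(p < 0 | p > 1)) abort("retention probabilities must lie in [0, 1]")
  withr::with_seed(seed, records[stats::runif(nrow(records)) < p, ])
}

#' Read / write fragment tables
#'
#' Fragment TSV dialect: columns `chrom`, `start`, `length`, `dup` (0/1),
#' `uniq` (0/1) and optionally `origin` (truth mode). Gzip-transparent via
#' readr.
#'
#' @param path file path.
#' @param records fragment tibble.
#' @return `read_fragments()` returns a fragment tibble;
#'   `write_fragments()` returns `path` invisibly.
#' @export
read_fragments <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "start", "length", "dup", "uniq")
  if (!all(need %in% names(x))) {
    abort(paste0("fragment file must have columns: ",
                 paste(need, collapse = ", ")))
  }
  out <- tibble::tibble(
    chrom = as.character(x$chrom),
    start = as.double(x$start),
    length = as.integer(x$length),
    is_duplicate = x$dup == 1,
    is_unique_mapping = x$uniq == 1
  )
  if ("origin" %in% names(x)) out$origin <- as.character(x$origin)
  assert_fragments(out)
}

#' @rdname read_fragments
#' @export
write_fragments <- function(records, path) {
  assert_fragments(records)
  out <- tibble::tibble(
    chrom = records$chrom, start = records$start, length = records$length,
    dup = as.integer(records$is_duplicate),
    uniq = as.integer(records$is_unique_mapping)
  )
  if ("origin" %in% names(records)) out$origin <- records$origin
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
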