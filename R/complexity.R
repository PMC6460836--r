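#' SNP-panel DNA complexity
#'
#' Library complexity proxy from captured sequencing of a SNP panel:
#' `complexity = total unique SNP-covering reads / panel size`. A
#' complexity of C means the library carries on average C distinct genome
#' copies' worth of molecules per locus.
#'
#' @param snp_counts vector of unique-read counts per covered SNP.
#' @param panel_size number of SNPs in the panel (default 300).
#' @return One-row tibble: `unique_snp_covering_reads`, `panel_size`,
#'   `complexity`.
#' @export
snp_complexity <- function(snp_counts, panel_size = 300) {
  if (panel_size <= 0) abort("panel_size must be > 0")
  if (any(snp_counts < 0)) abort("SNP read counts must be >= 0")
  tibble::tibble(
    unique_snp_covering_reads = sum(snp_counts),
    panel_size = panel_size,
    complexity = sum(snp_counts) / panel_size
  )
}

#' Closed-form expected duplication rate
#'
#' Drawing `n` reads uniformly with replacement from a pool of `M`
#' distinct molecules, the expected number of distinct molecules drawn is
#' `M (1 - (1 - 1/M)^n)`, so the expected duplication rate is
#' `1 - M (1 - (1 - 1/M)^n) / n`, with `M = round(C * G / L)` and
#' `n = round(d * G / L)` for complexity `C`, depth `d`, genome size `G`
#' and read length `L`.
#'
#' @param complexity input DNA complexity (genome copies in the pool).
#' @param depth sequencing depth (fraction of a genome sequenced).
#' @param genome_size genome size in bases.
#' @param read_length read length in bases.
#' @return Expected duplication rate (vectorised over
#'   `complexity`/`depth`).
#' @export
expected_duplication_rate <- function(complexity, depth,
                                      genome_size = 3.1e6,
                                      read_length = 150) {
  m <- round(complexity * genome_size / read_length)
  n <- round(depth * genome_size / read_length)
  if (any(m <= 0)) abort("pool size is zero; increase complexity or genome_size")
  if (any(n <= 0)) abort("no reads drawn; increase depth or genome_size")
  1 - m * (1 - (1 - 1 / m)^n) / n
}

#' Simulate sequencing duplication for a given library complexity
#'
#' Builds a virtual pool of `round(complexity * genome_size /
#' read_length)` distinct molecules, draws `round(depth * genome_size /
#' read_length)` reads with replacement, and reports the duplication rate
#' `1 - distinct/drawn`, averaged over `reps` replicates. Molecules are
#' abstract identifiers: a duplicate means the same source molecule drawn
#' twice.
#'
#' @inheritParams expected_duplication_rate
#' @param reps Monte-Carlo replicates.
#' @param seed integer seed.
#' @return One-row tibble: `complexity`, `depth`, `pool_size`, `n_reads`,
#'   `duplication_rate` (mean over reps), `rate_sd`, `expected_rate`,
#'   `reps`.
#' @export
simulate_duplication <- function(complexity, depth, genome_size = 3.1e6,
                                 read_length = 150, reps = 50, seed = 1) {
  m <- round(complexity * genome_size / read_length)
  n <- round(depth * genome_size / read_length)
  if (m <= 0) abort("pool size is zero")
  if (n <= 0) abort("no reads drawn")
  rates <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      ids <- ceiling(stats::runif(n) * m)  # uniform draw; supports m > 2^31
      1 - length(unique(ids)) / n
    }, double(1))
  })
  tibble::tibble(
    complexity = complexity, depth = depth, pool_size = m, n_reads = n,
    duplication_rate = mean(rates), rate_sd = stats::sd(rates),
    expected_rate = expected_duplication_rate(complexity, depth,
                                              genome_size, read_length),
    reps = reps
  )
}

#' Duplication-rate grid and minimum-complexity threshold
#'
#' Simulates the duplication rate over a grid of input complexities and
#' sequencing depths (the in-silico experiment motivating the minimum
#' complexity threshold for reliable low-depth screening), and finds the
#' smallest complexity whose mean rate stays at or below a ceiling at a
#' given depth.
#'
#' @param complexities,depths grid values.
#' @inheritParams simulate_duplication
#' @return `duplication_grid()`: tibble of class `dup_grid`, one row per
#'   grid cell (columns as [simulate_duplication()]).
#' @export
duplication_grid <- function(complexities = c(0.1, 0.5, 1, 2, 3, 5, 10, 30, 100),
                             depths = c(0.1, 0.25, 0.5, 1),
                             genome_size = 3.1e6, read_length = 150,
                             reps = 50, seed = 1) {
  if (length(complexities) == 0 || length(depths) == 0) {
    abort("empty grid")
  }
  grid <- tidyr::expand_grid(complexity = complexities, depth = depths)
  out <- purrr::pmap_dfr(grid, function(complexity, depth) {
    simulate_duplication(complexity, depth, genome_size, read_length, reps,
                         seed = derive_seed(seed, round(complexity * 1000 +
                                                          depth * 7)))
  })
  class(out) <- c("dup_grid", class(out))
  out
}

#' @rdname duplication_grid
#' @param grid a `dup_grid` tibble.
#' @param depth depth at which to scan.
#' @param rate_ceiling maximum acceptable mean duplication rate
#'   (default 2%).
#' @return `min_complexity()`: the smallest grid complexity meeting the
#'   ceiling (NA if none does).
#' @export
min_complexity <- function(grid, depth, rate_ceiling = 0.02) {
  sub <- grid[grid$depth == depth, ]
  if (nrow(sub) == 0) abort("depth not present in the grid")
  ok <- sub$complexity[sub$duplication_rate <= rate_ceiling]
  if (length(ok) == 0) return(NA_real_)
  min(ok)
}
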