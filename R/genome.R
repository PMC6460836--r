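# hg19 chromosome lengths (bases)
HG19_LENGTHS <- c(
  chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
  chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
  chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
  chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
  chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
  chr21 = 48129895, chr22 = 51304566, chrX = 155270560, chrY = 59373566
)

AUTOSOMES <- paste0("chr", 1:22)

#' Build a genome model for binned cfDNA analysis
#'
#' A genome model holds ordered chromosome lengths and a fixed tiling of
#' half-open bins (default 20 kb) with a GC fraction per bin. By default
#' chromosome lengths are hg19 scaled down by `scale`, which keeps relative
#' chromosome ratios (the quantity the screen works on) realistic while
#' keeping simulations desk-sized. Per-bin GC is a smooth deterministic
#' pattern spanning roughly 0.30-0.60 so that GC-bias injection and
#' correction act on a realistic dynamic range.
#'
#' @param scale divisor applied to hg19 chromosome lengths (default 1000).
#' @param bin_size bin width in bases (default 20000). The last bin of each
#'   chromosome may be partial.
#' @param chrom_lengths optional named vector of chromosome lengths (bases),
#'   overriding the scaled hg19 default.
#' @param bin_gc optional numeric vector of per-bin GC fractions in `[0, 1]`
#'   (length must equal the total bin count); default is the deterministic
#'   smooth pattern.
#' @return An object of class `genome_model`: a list with `chromosomes`
#'   (tibble: chrom, length), `bins` (tibble: chrom, bin_start, bin_end,
#'   width, gc) and `bin_size`.
#' @examples
#' gm <- genome_model()
#' gm$chromosomes
#' @export
genome_model <- function(scale = 1000, bin_size = 20000,
                         chrom_lengths = NULL, bin_gc = NULL) {
  if (is.null(chrom_lengths)) chrom_lengths <- round(HG19_LENGTHS / scale)
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    abort("chrom_lengths must be a named vector")
  }
  if (any(chrom_lengths <= 0)) abort("all chromosome lengths must be > 0")
  if (bin_size <= 0) abort("bin_size must be > 0")

  chroms <- tibble::tibble(
    chrom = names(chrom_lengths),
    length = as.double(unname(chrom_lengths))
  )
  bins <- purrr::map2_dfr(chroms$chrom, chroms$length, function(ch, len) {
    starts <- seq(0, len - 1, by = bin_size)
    tibble::tibble(
      chrom = ch,
      bin_start = starts,
      bin_end = pmin(starts + bin_size, len)
    )
  })
  bins$width <- bins$bin_end - bins$bin_start
  n <- nrow(bins)
  if (is.null(bin_gc)) {
    i <- seq_len(n)
    bin_gc <- 0.45 + 0.10 * sin(2 * pi * i / 23) + 0.05 * sin(2 * pi * i / 7 + 1)
  }
  if (length(bin_gc) != n) abort("bin_gc must have one value per bin")
  if (any(bin_gc < 0 | bin_gc > 1)) abort("bin_gc values must lie in [0, 1]")
  bins$gc <- as.double(bin_gc)

  structure(
    list(chromosomes = chroms, bins = bins, bin_size = bin_size),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model> ", nrow(x$chromosomes), " chromosomes, ",
      nrow(x$bins), " bins of ", x$bin_size, " bp (last bin may be partial)\n",
      sep = "")
  cat("  total size: ", format(sum(x$chromosomes$length), big.mark = ","),
      " bases\n", sep = "")
  invisible(x)
}

# expected per-bin sampling weight for one tissue, under a GC-bias curve.
# copy number: autosomes 2 (trisomy chromosome 3 in the fetal genome),
# X = 2 (female) or 1 (male), Y = 0 (female) or 1 (male).
genome_bin_weights <- function(genome, gc_bias = gc_bias_curve(),
                               sex = c("female", "male"), trisomy = "none") {
  sex <- match.arg(sex)
  bins <- genome$bins
  copy <- rep(2, nrow(bins))
  copy[bins$chrom == "chrX"] <- if (sex == "male") 1 else 2
  copy[bins$chrom == "chrY"] <- if (sex == "male") 1 else 0
  if (!identical(trisomy, "none")) {
    if (!trisomy %in% genome$chromosomes$chrom) {
      abort(paste0("unknown trisomy chromosome: ", trisomy))
    }
    copy[bins$chrom == trisomy] <- 3
  }
  w <- bins$width * copy * gc_bias(bins$gc)
  if (any(w < 0)) abort("GC-bias curve must be non-negative")
  w
}

#' Expected chromosome read share under the generator model
#'
#' Closed-form expected fraction of reads on one chromosome for a tissue of
#' given sex/trisomy state under a GC-bias curve, i.e. the bin-weight share
#' that [simulate_sample()] draws from. Used for chrY calibration and as an
#' oracle for ratio checks.
#'
#' @param genome a [genome_model()].
#' @param chrom chromosome name.
#' @param gc_bias GC-bias curve, a function of GC fraction.
#' @param sex `"female"` or `"male"`.
#' @param trisomy trisomic chromosome name or `"none"`.
#' @return Expected read fraction (scalar).
#' @export
expected_chrom_share <- function(genome, chrom, gc_bias = gc_bias_curve(),
                                 sex = c("female", "male"), trisomy = "none") {
  sex <- match.arg(sex)
  w <- genome_bin_weights(genome, gc_bias, sex, trisomy)
  sum(w[genome$bins$chrom == chrom]) / sum(w)
}

#' Read-count QC threshold scaled to the genome model
#'
#' Screening protocols require a minimum unique-read count per sample
#' (3.5 million for a full-size human genome). On a scaled-down genome the
#' same requirement is expressed per genome equivalent.
#'
#' @param genome a [genome_model()].
#' @param full_genome_reads required reads for a full hg19 genome.
#' @return Scaled minimum read count.
#' @export
scaled_min_reads <- function(genome, full_genome_reads = 3.5e6) {
  full_genome_reads * sum(genome$chromosomes$length) / sum(HG19_LENGTHS)
}
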