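# shared small fixtures; everything is generated in code at test time

toy_genome <- function(len1 = 100000, len2 = 50000, bin_size = 10000,
                       gc = NULL) {
  genome_model(chrom_lengths = c(chr1 = len1, chr21 = len2),
               bin_size = bin_size, bin_gc = gc)
}

# hand-built fragment tibble
frag_tbl <- function(chrom, start, length, dup = FALSE, uniq = TRUE,
                     origin = NULL) {
  out <- tibble::tibble(
    chrom = chrom, start = as.double(start), length = as.integer(length),
    is_duplicate = rep_len(dup, base::length(chrom)),
    is_unique_mapping = rep_len(uniq, base::length(chrom))
  )
  if (!is.null(origin)) out$origin <- origin
  out
}

# bin table with prescribed corrected counts (for ratio/reference tests)
ratio_table <- function(chr21_count, autosome_count, n_bins = 10) {
  tibble::tibble(
    sample_id = "x",
    chrom = c(rep("chr1", n_bins), "chr21"),
    bin_start = c(seq(0, by = 20000, length.out = n_bins), 0),
    gc = 0.45, width = 20000,
    raw_count = c(rep(autosome_count / n_bins, n_bins), chr21_count),
    corrected = c(rep(autosome_count / n_bins, n_bins), chr21_count),
    masked = FALSE
  )
}
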