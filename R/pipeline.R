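#' Pipeline configuration
#'
#' Thresholds and options for the screening pipeline, serializable to YAML
#' with [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param size_cutoff in-silico size-selection cutoff (bp).
#' @param z_cutoff z-score cutoff (strict).
#' @param ff_floor fetal-fraction no-call floor.
#' @param p_diff_max size-FF consistency ceiling.
#' @param min_length read-filter minimum length (bp).
#' @param full_genome_reads minimum unique reads per full genome
#'   equivalent.
#' @param min_reference minimum euploid reference samples.
#' @param ff_method fetal-fraction estimator: `"chry"` or `"size"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(size_cutoff = 160, z_cutoff = 3,
                            ff_floor = 0.04, p_diff_max = 0.40,
                            min_length = 50, full_genome_reads = 3.5e6,
                            min_reference = 20,
                            ff_method = c("chry", "size")) {
  cfg <- list(
    size_cutoff = size_cutoff, z_cutoff = z_cutoff, ff_floor = ff_floor,
    p_diff_max = p_diff_max, min_length = min_length,
    full_genome_reads = full_genome_reads, min_reference = min_reference,
    ff_method = match.arg(ff_method)
  )
  num <- unlist(cfg[c("size_cutoff", "z_cutoff", "ff_floor", "p_diff_max",
                      "min_length", "full_genome_reads", "min_reference")])
  if (any(num <= 0)) abort("every pipeline threshold must be positive")
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Per-sample pipeline statistics
#'
#' Reduces one sample's fragment table to the statistics the screen needs:
#' read filtering, in-silico size selection (enriched mode), binned
#' counting, unique-read count, chrY fetal-fraction estimate and size
#' features. Lets large cohorts be processed one sample at a time without
#' holding all fragments in memory; [run_pipeline()] is the cohort-level
#' wrapper.
#'
#' @param fragments fragment tibble of one sample.
#' @param genome a [genome_model()].
#' @param mode `"ordinary"` or `"enriched"`.
#' @param config a [pipeline_config()].
#' @param cal chrY calibration from [chry_calibration()].
#' @param sample_id identifier.
#' @return List: `table` (bin counts), `n_unique`, `ff_chry`, `r_a`,
#'   `r_b`, `sample_id`.
#' @export
pipeline_sample_stats <- function(fragments, genome,
                                  mode = c("ordinary", "enriched"),
                                  config = pipeline_config(),
                                  cal = chry_calibration(genome),
                                  sample_id = "s1") {
  mode <- match.arg(mode)
  fr <- filter_reads(fragments, min_length = config$min_length)
  if (mode == "enriched") fr <- size_select(fr, config$size_cutoff)
  sr <- size_ratios(fr)
  list(
    table = bin_counts(fr, genome, sample_id),
    n_unique = nrow(fr),
    ff_chry = ff_from_chry(fr, cal),
    r_a = sr$r_a, r_b = sr$r_b,
    sample_id = sample_id
  )
}

#' Score prepared samples against a reference
#'
#' GC-corrects the samples' bin tables as one sequencing run and applies
#' the calling rule to each. The streaming counterpart of
#' [run_pipeline()] for stats produced by [pipeline_sample_stats()].
#'
#' The intrarun normalization step assumes the run is predominantly
#' euploid (its per-bin median is the run's normal profile). Samples
#' screened outside a large euploid run should therefore be corrected
#' within a euploid `run_tables` context -- typically the bin tables of
#' the reference cohort, available as `attr(reference, "run_tables")`.
#'
#' @param stats list of [pipeline_sample_stats()] results (one run).
#' @param genome a [genome_model()].
#' @param reference protocol-matched [build_reference()] object.
#' @param config a [pipeline_config()].
#' @param size_model optional [train_size_ff_model()] fit (required for
#'   `ff_method = "size"`).
#' @param run_tables optional list of euploid bin-count tables joining
#'   the run for GC correction (not called).
#' @return Tibble of [call_sample()] rows.
#' @export
screen_samples <- function(stats, genome, reference,
                           config = pipeline_config(), size_model = NULL,
                           run_tables = NULL) {
  if (is.null(reference)) {
    abort(paste0("no reference supplied; build one from euploid controls ",
                 "with build_run_reference()"))
  }
  if (config$ff_method == "size" && is.null(size_model)) {
    abort("ff_method = 'size' requires a trained size_model")
  }
  min_reads <- scaled_min_reads(genome, config$full_genome_reads)
  corrected <- gc_correct_run(c(purrr::map(stats, "table"), run_tables))
  corrected <- corrected[seq_along(stats)]
  purrr::map_dfr(seq_along(stats), function(i) {
    st <- stats[[i]]
    if (config$ff_method == "chry") {
      ff <- st$ff_chry
      predictable <- TRUE
    } else {
      est <- estimate_ff_size(size_model, st$r_a, st$r_b, config$p_diff_max)
      ff <- est$ff
      predictable <- est$predictable
    }
    call_sample(corrected[[i]], reference, ff = ff, n_unique = st$n_unique,
                min_reads = min_reads, ff_floor = config$ff_floor,
                z_cutoff = config$z_cutoff, ff_predictable = predictable,
                sample_id = st$sample_id)
  })
}

#' Run the screening pipeline on a simulated cohort
#'
#' Composes the analysis stages in protocol order for every sample of a
#' cohort: read filtering, in-silico size selection (enriched mode only),
#' binned counting, three-step GC correction (treating the cohort as one
#' sequencing run), fetal-fraction estimation, and z-score calling
#' against a euploid reference built under the same mode with
#' [build_run_reference()].
#'
#' @param cohort cohort tibble from [simulate_cohort()].
#' @param genome a [genome_model()].
#' @param reference a [build_reference()] object, protocol-matched to
#'   `mode`.
#' @param mode `"ordinary"` or `"enriched"`.
#' @param config a [pipeline_config()].
#' @param gc_bias GC-bias curve the samples were generated under (used
#'   only for chrY calibration).
#' @param size_model optional [train_size_ff_model()] fit; required when
#'   `config$ff_method == "size"`.
#' @param run_tables optional euploid run context for GC correction (see
#'   [screen_samples()]); defaults to the reference cohort's bin tables
#'   when the reference carries them and the cohort itself is small.
#' @return Tibble of [call_sample()] rows, one per sample.
#' @export
run_pipeline <- function(cohort, genome, reference,
                         mode = c("ordinary", "enriched"),
                         config = pipeline_config(),
                         gc_bias = gc_bias_curve(), size_model = NULL,
                         run_tables = NULL) {
  mode <- match.arg(mode)
  cal <- chry_calibration(genome, gc_bias)
  stats <- purrr::map(seq_len(nrow(cohort)), function(i) {
    pipeline_sample_stats(cohort$fragments[[i]], genome, mode, config, cal,
                          sample_id = cohort$sample_id[i])
  })
  if (is.null(run_tables) && nrow(cohort) < 8) {
    run_tables <- attr(reference, "run_tables")
  }
  screen_samples(stats, genome, reference, config, size_model, run_tables)
}

#' Build a protocol-matched euploid reference from a control cohort
#'
#' Applies the same preprocessing as [run_pipeline()] (same mode, same
#' run-level GC correction) to a euploid control cohort and returns the
#' [build_reference()] statistics.
#'
#' @inheritParams run_pipeline
#' @param chroms chromosomes to reference.
#' @return A `nips_reference`.
#' @export
build_run_reference <- function(cohort, genome,
                                mode = c("ordinary", "enriched"),
                                config = pipeline_config(),
                                gc_bias = gc_bias_curve(),
                                chroms = c("chr13", "chr18", "chr21")) {
  mode <- match.arg(mode)
  if (any(cohort$trisomy != "none")) {
    abort("reference cohort must contain only euploid samples")
  }
  cal <- chry_calibration(genome, gc_bias)
  stats <- purrr::map(seq_len(nrow(cohort)), function(i) {
    pipeline_sample_stats(cohort$fragments[[i]], genome, mode, config, cal,
                          sample_id = cohort$sample_id[i])
  })
  tables <- purrr::map(stats, "table")
  corrected <- gc_correct_run(tables)
  ref <- build_reference(corrected, chroms = chroms,
                         min_samples = config$min_reference)
  # raw bin tables kept so test samples can borrow this euploid run as
  # their intrarun-normalization context
  attr(ref, "run_tables") <- tables
  ref
}

#' The 11-sample false-negative validation cohort
#'
#' Validation set of eleven confirmed-trisomy pregnancies whose original
#' screens were falsely negative: karyotype, fetal fraction (%) and
#' trisomy-chromosome z-score under the ordinary protocol and after
#' short-fragment enrichment. Shipped as a plain-text fixture; used to
#' check the calling rule's rescue behaviour.
#'
#' @return Tibble with columns `sample`, `karyotype`, `trisomy`,
#'   `ff_ordinary_pct`, `z_ordinary`, `ff_enriched_pct`, `z_enriched`.
#' @export
false_negative_cohort <- function() {
  path <- system.file("extdata", "false_negative_cohort.tsv",
                      package = "cffenrich")
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
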