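# cffenrich

Simulation and analysis toolkit for noninvasive prenatal screening (NIPS)
from maternal-plasma cell-free DNA (cfDNA), with **short-fragment
enrichment** of the fetal compartment.

## The problem

NIPS calls fetal trisomies 13/18/21 from the excess of sequencing reads on
the trisomic chromosome. For a sample with fetal fraction *f*, the
chromosome ratio

  r = (corrected reads on the chromosome) / (corrected autosomal reads)

is elevated by the factor (1 + *f*/2) relative to euploid pregnancies, and
is standardized against a euploid reference set:

  z = (r − μ_ref) / σ_ref,  positive call when z > 3 (strict).

Reliability collapses at low fetal fraction: below the conventional 4%
floor the sample is a no-call, and just above it trisomies are missed.
Fetal (placental) cfDNA is shorter than maternal cfDNA — a reduced ~166 bp
chromatosome peak and more fragments under 150 bp — so keeping only
fragments **< 160 bp** roughly doubles the fetal fraction and rescues
low-FF samples. This package implements the full screen, both with and
without enrichment, plus the supporting estimators:

- `simulate_sample()` / `simulate_cohort()` — seeded cfDNA fragment
  cohorts: distinct maternal/fetal size distributions, GC sampling bias,
  per-chromosome biological dispersion, chrY dosage by fetal sex, trisomy
  dosage, duplicate/multi-map injection. The truth channel (`origin`) is
  never read by analysis code.
- `filter_reads()` → `size_select()` / `simulate_bead_enrichment()` →
  `bin_counts()` → `gc_correct_run()` (LOESS + intrarun + quadratic
  regression) → `build_reference()` / `call_sample()` — the pipeline;
  `run_pipeline()` composes it for a cohort.
- `ff_from_chry()` and `train_size_ff_model()` / `estimate_ff_size()` —
  fetal fraction from the chrY read share, and from fragment-size features
  (regions [130,140) and [155,175) bp) with the P_diff consistency rule:
  P_diff = (P_A − P_B) · 2/(P_A + P_B), unpredictable when |P_diff| > 0.40.
- `snp_complexity()`, `simulate_duplication()`, `duplication_grid()` —
  library-complexity statistic and the sampling model giving the
  duplication rate 1 − M(1 − (1 − 1/M)^n)/n; minimum usable complexity ≈ 3
  at 0.1× depth under a 2% duplication ceiling.
- `confusion_metrics()`, `wilson_ci()`, `compare_rates()`,
  `evaluate_cohort()` — screening performance with Wilson 95% CIs and
  chi-square/Fisher rate tests.

## Worked example

Simulate a euploid reference run and a low-fetal-fraction trisomy-21
sample, then screen it with and without in-silico enrichment:

```r
library(cffenrich)

gm  <- genome_model()            # hg19 / 1000, 20-kb bins
cfg <- pipeline_config()         # 160 bp cutoff, z > 3, 4% FF floor

ref_cohort <- simulate_cohort(gm, 20, seed = 11, n_fragments = 1.5e6,
                              prevalence = 0)
ref_ord <- build_run_reference(ref_cohort, gm, mode = "ordinary")
ref_enr <- build_run_reference(ref_cohort, gm, mode = "enriched")

tri <- simulate_cohort(gm, 1, seed = 202, n_fragments = 1.5e6,
                       fixed_ff = 0.045, prevalence = 1, p_male = 1)
ordinary <- run_pipeline(tri, gm, ref_ord, mode = "ordinary")
enriched <- run_pipeline(tri, gm, ref_enr, mode = "enriched")

ordinary[, c("z_chr21", "ff", "decision")]
#>   z_chr21     ff decision
#> 1    1.45  0.042 negative      <- a false negative at FF ~4%
enriched[, c("z_chr21", "ff", "decision")]
#>   z_chr21     ff decision
#> 1    3.29  0.122 positive      <- FF tripled by selection; z clears 3

tidy(ref_ord)
#>   chrom     mu       sd     n
#> 1 chr13 0.0376 0.000319    20
#> 2 chr18 0.0225 0.000206    20
#> 3 chr21 0.0150 0.000200    20
```

The `ff` column in enriched mode is the post-selection fetal fraction
(the chromosome-Y read share rescaled by `chry_calibration()`), and
`decision` applies the strict z > 3 rule after the read-count and
FF-floor QC gates: the same sample flips from a missed trisomy 21 to a
positive call. The run takes about two minutes (40 samples at 1.5 million
fragments). `autoplot()` methods draw the length-bin fold-change profile
(`binwise_ff_foldchange()`) and the duplication-rate grid
(`duplication_grid()`).

Screening-table statistics are reproduced from cohort counts alone:

```r
confusion_metrics(confusion_counts(
  n_total = 1404, n_fail = 10, true_positive = 5, test_positive = 8,
  called_negative = 1394, condition_negative = 1397, condition_positive = 5
))
#> sensitivity 100% (56.55–100), specificity 99.79% (99.37–99.93),
#> PPV 62.5% (30.6–86.3), NPV 100% (99.73–100), failure rate 0.71%
```

## Scope

The simulator works on a scaled-down genome (hg19/1000) with the read-count
QC expressed per genome equivalent. It emulates fragment-level statistics,
not sequence content: no alignment, mappability, placental mosaicism or
sub-chromosomal events. See `vignettes/methods.Rmd` for the model,
parameter choices, and what the synthetic experiments do and do not show.
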