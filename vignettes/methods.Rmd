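---
title: "Methods: simulating and screening size-enriched cfDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and screening size-enriched cfDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cffenrich)
```

## The problem

Noninvasive prenatal screening (NIPS) detects fetal trisomies 13, 18 and 21
from shallow sequencing of maternal-plasma cell-free DNA (cfDNA). The signal
is a small excess of reads on the trisomic chromosome, proportional to half
the fetal fraction (FF): a trisomic sample's chromosome ratio is elevated by
the factor $(1 + f/2)$, where $f$ is the FF. Because the placental (fetal)
compartment is typically only 3-30% of plasma cfDNA, samples with low FF
produce test failures ("no-calls", conventionally below a 4% FF floor) and
false negatives.

Fetal cfDNA is systematically shorter than maternal cfDNA: maternal
fragments peak at the chromatosome-protected length (~166 bp), while the
fetal compartment has a reduced 166 bp proportion and more fragments below
150 bp. Selecting fragments shorter than 160 bp therefore enriches the
fetal compartment roughly two-fold — enough to pull borderline samples
over the 4% floor and rescue low-FF false negatives. This package
implements that screen end to end: a seeded fragment-cohort simulator, the
read-filtering/size-selection/GC-correction/z-score pipeline, two FF
estimators, a library-complexity model, and the performance statistics
used to evaluate the ordinary and enriched protocols side by side.

## The generator

`simulate_sample()` draws aligned fragment records (chromosome, 0-based
start, length, duplicate and mapping flags) rather than reads: alignment
and base-level quality are upstream of the model. Each fragment is fetal
with probability $f$; its bin is drawn proportional to
bin width x copy number x GC bias, its start uniformly within the bin,
and its length from the compartment's size distribution. A trisomic
chromosome has copy number 3 in the fetal compartment (1.5x weight); male
fetuses carry one X and one Y. Duplicates are injected by re-emitting
existing records (default 2%), and a configurable fraction of records is
flagged as multi-mapping (default 1%).

**Genome.** The default genome is hg19 with every chromosome scaled down
by 1000 (bins of 20 kb as in the analysis pipeline, ~166 bins in total).
Scaling preserves relative chromosome sizes — the quantity the screen
measures — while keeping cohort simulation fast. The minimum-read QC is
expressed per genome equivalent (`scaled_min_reads()`), so the protocol's
3.5-million-read requirement keeps its meaning on the scaled genome.
Per-bin GC is a smooth deterministic pattern spanning ~0.30-0.60.

**Size distributions.** Fragment lengths are drawn from four-component
mixtures on 50-250 bp: a sharp chromatosome peak N(166, 4), a nucleosome
peak (N(143, 7) maternal, N(141, 10) fetal — the fetal peak slightly
shorter and broader), a uniform sub-nucleosomal tail on 100-140 bp, and
a broad long-fragment shoulder N(190, 20) (the rising edge toward
di-nucleosomal lengths). Weights are 0.84/0.10/0.04/0.02 (maternal) and
0.42/0.50/0.07/0.01 (fetal). No parametric form for these distributions
is established; the parameters were fitted once against the qualitative
fragmentomics the analysis relies on: (i) the fetal distribution places
more mass below 150 bp (0.47 vs 0.12); (ii) the length-binned
chrY-fraction fold-change profile rises about two-fold from the
[100,110) bin to an interior peak at 120-140 bp, stays above 1 in every
bin below 160 bp (≈1.6 at [150,160)) and falls below 1 from 160 bp on —
the shape of published fold-change profiles; (iii) selecting fragments
< 160 bp roughly doubles the fetal fraction (factor ~1.9-2.9 across FF
3-30%, ~2.5 at a typical 11%). A small maternal sub-nucleosomal
component is required for (ii): without it the shortest bin would have
unbounded fold change and the profile could not rise to an interior
peak. The maternal-dominated shoulder keeps the bins above 180 bp
populated with fold change below 1.

**Between-sample dispersion.** With purely multinomial sampling, a euploid
reference at 3.5 million reads would have a chromosome-ratio SD of about
7e-5 — so tight that the *ordinary* screen would already flag trisomies at
FF below 4%, which contradicts how such samples present clinically as
false negatives. Published z-scores at known FF (e.g. z = 2.41 at FF 5.6%
on the trisomic chromosome) imply a reference-set relative SD of ~1.2% at
that depth, about 2.7x counting noise. The generator therefore applies a
per-sample, per-chromosome log-normal representation factor with CV 1%
(`bio_cv`), shared by the maternal and fetal compartments, emulating the
biological and technical between-sample variability that dominates deep-
sequencing chromosome ratios. All z-score behaviour in the tests
(detection at moderate FF, misses just below the floor, rescue after
enrichment) emerges from this dispersion plus counting noise.

**Bead enrichment.** Physical size selection is modelled as independent
Bernoulli retention with a logistic curve decreasing in length, midpoint
160 bp (`bead_retention_curve()`). The three presets ("1.2x", "1.3x",
"1.5x" bead ratios, scale 12/8/4 bp) differ only in steepness; 1.5x is
closest to the hard in-silico cutoff `size_select()`. A step-function
retention reproduces `size_select()` exactly.

## The analysis pipeline

Stages run in protocol order (`run_pipeline()`, or
`pipeline_sample_stats()` + `screen_samples()` for streaming cohorts):

1. **Read filters** (`filter_reads()`): drop fragments shorter than 50 bp,
   then non-unique mappers, then duplicates. Flag-marked duplicates are
   removed before key-based deduplication on (chrom, start, length), which
   makes the unique-read count invariant under record permutation. The
   survivors are the "unique reads".
2. **Size selection** (`size_select()`, enriched mode): keep fragments
   strictly below 160 bp.
3. **Binned counting** (`bin_counts()`): fragments are assigned to the
   20-kb bin containing their start.
4. **GC correction** (`gc_correct_run()`), three steps, each preserving
   the sample's unmasked total: (i) per-sample LOESS of count on GC (span
   0.75, degree 2 — the standard defaults), dividing each bin by its
   fitted value times the genome-median count; (ii) intrarun
   normalization — each bin divided by the run-median of its step-(i)
   value, which assumes the run is predominantly euploid and therefore
   requires at least 8 samples (skipped, with a warning, otherwise);
   (iii) a quadratic regression on GC and GC^2 whose fitted component is
   subtracted, with counts floored at zero. Masked bins (sex chromosomes,
   partial end bins, GC outside 0.2-0.8, non-positive LOESS fit, zero run
   median) are excluded from every ratio. Sex chromosomes are masked
   because their dosage varies with fetal sex and fraction, so a
   GC-indexed smoother would treat them as outliers.
5. **z-scores and calls** (`build_reference()`, `call_sample()`): the
   chromosome ratio is the corrected-count share of a chromosome among
   unmasked autosomal bins; z is standardized against the mean and n-1 SD
   of a euploid reference (>= 20 samples, protocol-matched: enriched
   samples are scored against an enriched reference, since selection
   changes both the mean ratio and its spread). A sample is positive for
   a chromosome when z > 3 (strictly); it is a no-call when unique reads
   fall below the scaled 3.5M equivalent, the FF estimate is below 4%, or
   the size-based FF is inconsistent.

## Fetal-fraction estimators

`ff_from_chry()` linearly rescales the chrY read share between the
female-pregnancy baseline `b_f` and the pure-male-tissue share `y_m`
(male fetuses only). Both constants come in closed form from the genome
model's bin weights under the GC-bias curve in effect — the exact value
of what a calibration cohort would estimate; a simulated cross-check is
in the test suite.

`estimate_ff_size()` works for either fetal sex: the read fractions in a
short window (region A, [130, 140) bp, fetal-enriched) and a long window
(region B, [155, 175) bp, maternal-enriched) are mapped to FF through two
LOESS curves trained on male-fetus samples labelled by the chrY estimator
(`train_size_ff_model()`). The two predictions are combined as
P = (P_A + P_B)/2 when consistent. Consistency uses
P_diff = (P_A − P_B) x 2/(P_A + P_B), reported signed (anti-symmetric
under feature swap) but thresholded on |P_diff| > 0.40 — a signed rule
would never flag P_B >> P_A. The 0.40 ceiling sits above the 99th
percentile of P_diff in normal cohorts, which the test suite verifies on
a 500-sample simulation. Predictions outside a feature's training range
are clamped to the range edge and flagged.

## Library complexity and duplication

Enrichment discards most input molecules, so the complexity of the
library (distinct genome copies) limits how deep it can be sequenced
before duplicates dominate. `simulate_duplication()` draws
n = depth x genome/150 reads with replacement from a pool of
M = complexity x genome/150 molecules; the closed-form expectation of the
duplication rate is $1 - M\,(1-(1-1/M)^n)/n$, and the simulation agrees
with it within Monte-Carlo error at every grid cell. At 0.1x depth the
expected rate crosses a 2% ceiling between complexity 2 (2.5%) and 3
(1.65%), which is why `min_complexity()` on the default grid returns 3 —
the minimum input complexity for reliable low-depth screening.
`snp_complexity()` computes the empirical statistic (unique SNP-covering
reads / panel size, default 300 SNPs).

## Performance evaluation

`confusion_metrics()` reports sensitivity, specificity, PPV, NPV and the
failure rate with Wilson score intervals, the interval that reproduces
published screening CIs at small numerators; percentages round half-up to
two decimals. No-calls count as failures and are excluded from every
metric denominator. Because cohort tables do not always carry a separate
condition-positive margin, `confusion_counts()` takes it explicitly and
derives false positives/negatives. `compare_rates()` uses the Pearson
chi-square *without* continuity correction (the corrected statistic is
conservative enough to flip borderline failure-rate comparisons past
p = 0.01) or Fisher's exact test when expected cells drop below 5.

## Numerical and design choices

- Coordinates are 0-based, half-open throughout; length windows and bins
  are half-open; the z cutoff and the P_diff ceiling are strict
  inequalities (z = 3 exactly is negative; P_diff = 0.40 exactly is
  predictable).
- Fragments are assigned to bins by start coordinate (not midpoint).
- Reads outside [100, 200) contribute to pooled chrY fractions but not to
  the ten length bins of the fold-change table; an empty bin reports a
  missing fold change, never zero.
- Per-sample RNG streams derive deterministically from a single master
  seed; cohorts are byte-reproducible.
- The fold-change analysis pools samples into mixed sets (default 100
  samples) and averages per-set profiles; a pooled single-set mode is
  also available.
- Degenerate inputs fail loudly: zero-SD references, zero denominators,
  empty grids and malformed records raise errors rather than propagate.

## Problem sizes used by the test suite

Simulation depth is matched to what each check measures. Distribution-
shape checks (fold-change profile, FF gain, estimator recovery) use
5e4-1e5 fragments per sample, where counting noise is far below the
effect sizes. z-score checks need depth: the rescue experiment uses the
protocol's 3.5 million fragments per sample, 20-sample protocol-matched
references, and 20 trisomy-21 replicates at FF 3.8%, asserting that a
majority convert from a missed result to a positive call after
enrichment. The P_diff ceiling check uses 500 samples at 1e5 fragments.

## What the synthetic tests do and do not show

The generator reproduces the statistical structure the method relies on —
two size distributions, GC bias, chromosomal dosage, counting and
between-sample dispersion, duplicate injection — but not sequence-level
reality: no mappability or repeat structure, no GC dependence of
*fragment length*, no confined placental mosaicism or maternal CNVs, a
single bias shape per run, and fetal sex/trisomy limited to whole
chromosomes 13/18/21. Passing tests therefore demonstrate that the
implementation is a faithful, internally consistent realization of the
screening method under its stated assumptions — not that clinical
cohort-level numbers (mean FF gain, exact fold-change magnitudes,
complexity losses) are reproduced, since those depend on undeposited
clinical data.
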