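Package: cffenrich
Title: In Silico Size Selection and Fetal Fraction Enrichment for cfDNA
    Prenatal Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for noninvasive prenatal
    screening (NIPS) from maternal-plasma cell-free DNA with short-fragment
    enrichment. Generates seeded cfDNA fragment cohorts with distinct
    maternal and fetal fragment-size distributions, GC sampling bias and
    duplicate reads; applies post-alignment read filters, in silico size
    selection (< 160 bp) and a stochastic bead-retention analogue; performs
    20-kb binned counting with three-step GC correction (LOESS, intrarun
    normalization, quadratic regression); calls whole-chromosome trisomies
    13/18/21 by chromosome-ratio z-scores against a euploid reference;
    estimates fetal fraction from chromosome-Y read share and from
    fragment-size features with a consistency rule; quantifies library
    complexity and duplication rates by sampling simulation; and evaluates
    screening performance with Wilson confidence intervals and rate
    comparison tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
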