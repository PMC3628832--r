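Package: idpcohort
Title: Intrinsic Disorder Cohort Analysis for Protein Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cohort-level analysis of intrinsic disorder in protein sets:
    per-residue disorder profiles from amino-acid propensity scales
    (including sliding-window charge-hydropathy unfoldability), whole-protein
    binary order/disorder classification by charge-hydropathy (CH) plots and
    cumulative distribution function (CDF) analysis, CH-CDF quadrant
    phase-space classification, fractional-difference amino-acid composition
    profiling with bootstrap confidence intervals, long-disordered-region and
    disorder-based binding-site (MoRF/ANCHOR) interval statistics, and a
    two-state segmental simulator that generates cohorts with known
    ground-truth disorder for end-to-end validation. Ships a curated
    annotation table of 109 yeast spliceosomal proteins as a worked dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
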