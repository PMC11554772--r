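Package: keapscreen
Title: Benchmarking Single-Marker and Two-Stage Screening Tests for
    KEAP1/NFE2L2 Pathway Activation in NSCLC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to benchmark single-marker diagnostic tests (normalized
    RNA expression of NFE2L2 target genes, NQO1 immunohistochemistry
    H-scores) and two-stage screen-then-validate combinatorial tests for
    predicting KEAP1/NFE2L2 mutation status and pathway activation in
    non-small-cell lung cancer. Includes ROC construction, AUC with
    stratified percentile-bootstrap confidence intervals, cutpoint
    optimization by Youden's J or by maximal sensitivity under a minimum
    specificity constraint, AND-composition of a cheap screening test with
    a fixed high-accuracy validator, a K1N2-testing cost-reduction metric,
    a seeded synthetic cohort generator emulating a mutation-enriched NSCLC
    cohort, and a reproducible end-to-end benchmark pipeline.
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
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
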