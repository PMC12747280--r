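Package: placentrace
Title: Placental Cell-Type Signatures and Their Trace in Maternal Circulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives cell-type-specific mRNA signatures of preeclampsia from
    placental single-cell RNA-seq data by pseudo-bulk negative binomial
    differential expression with explicit cell- and sample-level filters, and
    projects those signatures into maternal circulating transcriptomes and
    proteomes. Provides reference-anchored Z-score standardization,
    gestational-age detrending (mixed-effects B-splines, linear residuals, and
    regression-spline GAM dialects), probe/aptamer-to-gene collapsing,
    per-sample signature scoring, longitudinal trend tests, ROC/AUC
    discrimination with DeLong confidence intervals, and per-window t-tests.
    Includes a synthetic-data generator with planted effects so the whole
    pipeline is testable without access to restricted clinical datasets.
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
    lme4,
    MASS,
    Matrix,
    methods,
    mgcv,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    DESeq2,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
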