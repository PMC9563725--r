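Package: mtfr
Title: Multitask Sparse Factor Regression for miRNA-mRNA Regulatory Module Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns tissue-shared and cohort-specific miRNA-mRNA regulatory
    modules from matched expression matrices of multiple cancer cohorts by
    multitask sparse reduced-rank (factor) regression with an elastic-net
    penalty. The coefficient matrix of each cohort is factored into a block
    shared across cohorts and a cohort-private block; each rank-one component
    is a regulatory module linking a small set of miRNAs to a small set of
    mRNAs. Includes prox-linear block-coordinate optimization with automatic
    rank estimation, four-fold cross-validation for the penalty weights,
    module extraction with importance weights and feature selection,
    survival-based module filtering (2-means stratification plus log-rank
    test), a transcription-factor permutation test, and a synthetic-data
    generator with planted module structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
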