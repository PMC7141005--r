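Package: immunodecon
Title: Immune Cell Abundance from Bulk Expression via Signature
    Enrichment with Spillover Compensation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the relative abundance of 24 immune cell types
    (including 18 T-cell subsets) from bulk gene-expression profiles.
    Each sample's marker-gene deviation from a reference expression
    matrix is scored per cell type with a single-sample gene set
    enrichment statistic, and scores are calibrated with a compensation
    matrix via non-negative least squares to correct for marker genes
    shared between cell types.  Also provides simulation-driven marker
    selection from covariance-preserving mixtures with known fractions,
    synthetic reference bundles and pseudo-bulk construction from
    labelled single cells for benchmarking, a correlation-deviation
    evaluation statistic, and an immunotherapy-response classifier
    (RBF-SVM with sequential backward feature selection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    withr,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
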