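Package: deconvbench
Title: Benchmarking Reference-Based Cell-Type Deconvolution with
    Mean-Ratio Marker Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A toolkit for benchmarking reference-based cell-type
    deconvolution of bulk RNA-seq against orthogonal imaging-derived
    proportions. Implements the Mean Ratio marker-gene selection
    statistic and one-vs-all differential ranking, baseline
    non-negative least squares and marker-ratio proportion estimators
    with cell-size adjustment, evaluation metrics (Pearson correlation,
    rmse, relative rmse, within-block relative standard deviation),
    Fisher enrichment of marker genes in differentially quantified gene
    sets, equal-proportion reference resampling, quantification of
    segmented-cell imaging tables, and a synthetic-data generator with
    planted markers, cell-size factors and library-preparation biases
    so every stage is testable without external data.
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
    Matrix,
    methods,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
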