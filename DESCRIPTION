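Package: mirnorm
Title: Stable Reference Selection and Normalization for Circulating miRNA qPCR Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Identifies stable endogenous reference miRNAs in circulating-miRNA
    qPCR panels and normalizes such data. Implements spike-in and minimum-Ct
    relative quantification, Ct censoring and outlier flagging, per-group
    detection filtering, k-nearest-neighbour imputation on the log2 scale, and
    pseudo-detectors built from per-sample central tendencies. Candidate
    references are ranked by combining geNorm-style stepwise pairwise-variation
    M values, a model-based intra/intergroup variance stability estimate, and a
    coefficient-of-variation score into a summarized stability score (SSS).
    Includes normalization-factor construction from selected references or
    global central tendencies, evaluation via CV cumulative-distribution curves
    and PCA of autoscaled data, cross-platform score combination, and a
    synthetic serum-miRNA qPCR simulator with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
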