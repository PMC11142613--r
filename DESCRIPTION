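Package: madfc
Title: Mirrored Axis Distortion Plots for Fold Change Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Visualization toolkit for fold change data built around the
    mirrored axis distortion (MAD-FC) transform, a piecewise transform that
    mirrors sub-unit fold changes to negative reciprocals and contracts both
    branches one unit toward zero, yielding an axis that is readable,
    proportional in fold-change units, and symmetric about the point of no
    change. Provides the transform family and its exact inverse, a ggplot2
    coordinate scale with back-transformed tick labels (fraction, decimal, or
    exponent style), a diverging color normalization for heatmaps, builders
    for volcano, MA, interval, box, violin, and heatmap displays of
    differential-expression results, numeric audits of transform
    proportionality, symmetry, and pixel-budget dynamic range, and seeded
    synthetic generators for fold-change fixtures and DESeq2-style results
    tables.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    scales,
    stats,
    tibble,
    tidyr,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
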