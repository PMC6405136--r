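Package: texrepro
Title: Reproducibility of MRI Texture Radiomics Features Under Gray-Level
    Discretization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how gray-level discretization (fixed bin size
    versus fixed bin number) affects the inter- and intra-observer
    reproducibility of 2D texture radiomics features. Implements both
    discretization rules, gray-level co-occurrence, run-length, size-zone,
    dependence and neighbourhood gray-tone difference matrices with two
    aggregation conventions, reproducibility-based feature selection by
    intraclass correlation and Lin's concordance coefficients, a simulator
    of delineation variability with Dice-stratified mask selection, and a
    synthetic multi-sequence study generator that emulates a two-reader,
    three-session reading design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    readr,
    rlang,
    RNifti,
    png,
    stats,
    tibble,
    tools,
    utils,
    tidyr,
    yaml
Suggests:
    jsonlite,
    purrr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
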