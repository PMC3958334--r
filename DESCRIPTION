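Package: mapkscreen
Title: Analysis of Quantitative RNAi Screens for RAS/MAPK Pathway Regulators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing genome-wide RNAi screens that read out
    RAS/MAPK pathway activity by quantitative phospho-MAPK immunofluorescence.
    Provides plate normalization to in-plate negative controls with Z'-factor
    quality control, reproducibility-based hit calling with a promoter-system
    false-positive filter, assignment of candidate regulators to epistasis
    intervals (RAS-RAF, RAF-MEK, MEK-MAPK) by weighted uncentered Pearson
    correlation against predetermined pathway profiles, composite specificity
    scoring, hierarchical clustering of functional profiles, qPCR log2-ratio
    differential-expression calls, and classification of splice-isoform ORF
    consequences (normal, truncated, frameshifted). A synthetic-screen
    generator with known ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
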