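Package: clonetrace
Title: Clonal Barcoding and Limiting-Dilution Analysis of Hematopoietic
    Transplants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of lentiviral cellular-barcoding and limiting-dilution
    transplantation experiments in fetal hematopoiesis. Provides simulation of
    barcoding libraries and dose-titration transplants, read-threshold and
    PCR-replicate-concordance filtering of barcode count tables,
    counts-per-million normalization, classification of clonal fates over the
    B-cell, erythroid, monocyte and neutrophil lineages with fate-frequency
    histograms, Pearson fate-similarity matrices and relative lineage biomass,
    single-hit Poisson maximum-likelihood estimation of repopulating-unit
    frequency with profile-likelihood confidence intervals, subfraction and
    pool-size arithmetic, and engraftment calling with Fisher's exact
    contingency comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
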