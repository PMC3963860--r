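Package: receptoire
Title: Comparative GPCR Repertoire Profiling from qPCR Arrays with
    Proteomic Concordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative expression profiling of the endo-GPCR
    repertoire across cell types from TaqMan low-density-array qPCR data:
    reference-gene stability scoring (geNorm-style M), delta-Ct
    normalization with expression units and cutoff filtering, cell-type
    specificity classification, from-scratch average-linkage hierarchical
    clustering of expression signatures, an in-silico tryptic-digestion
    predictor of MS-detectable peptides, and transcript/spectral-count
    concordance scoring. Includes a synthetic-data generator with known
    ground truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
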