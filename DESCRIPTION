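Package: ffpeqc
Title: RNA Quality and Expression Concordance Metrics for FFPE Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quality assessment and reliability metrics for gene expression
    data derived from formalin-fixed paraffin-embedded (FFPE) tissue.
    Computes DV200 fragment-size quality scores from capillary
    electrophoresis traces, flags putative cross-linked high-molecular-weight
    species, summarises per-gene reproducibility as coefficients of
    variation, quantifies concordant relative gene expression between paired
    sample groups or platforms at configurable fold-change cut-offs, compares
    expression ranks of top-expressed genes, measures transcriptome-wide
    3'/5' signal bias, and summarises qPCR quantification cycles. A
    synthetic-data generator with known ground truth emulates paired
    fresh-frozen/FFPE study designs so every stage is testable without
    access to array repositories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
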