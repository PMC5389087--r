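Package: sdscape
Title: Segmental Duplication Detection, Copy-Number Estimation and
    Enrichment Analysis on Synthetic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects segmental duplications (SDs) by whole-genome
    self-alignment (WGAC) and by excess mapped read depth (WSSD), combines
    the two lines of evidence with the 94 percent identity artifact-removal
    rule, estimates absolute copy numbers, tests SD maps for enrichment
    against genomic landmarks (CNVRs, pericentromeric and subtelomeric
    regions, gene families) by interval permutation, and summarizes
    duplicated gene content. Ships a synthetic-genome simulator that plants
    duplications with known identity and copy number so the whole pipeline
    is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    stats,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
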