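Package: caprimir
Title: Small RNA and mRNA Expression Profiling for Developing Caprine
    Skeletal Muscle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable reimplementation of a two-library small
    RNA / mRNA sequencing analysis for developing skeletal muscle:
    library accounting and sequence-composition profiling, an exact
    two-library Poisson (Audic-Claverie) differential-expression test
    with Benjamini-Hochberg FDR, novel-miRNA hairpin screening built on
    a self-contained nearest-neighbour minimum-free-energy folding
    engine (MFE/AMFE/MFEI filter battery), rule-based miRNA to 3'UTR
    target scoring, and a miRNA-mRNA integration stage (DE-target
    intersection, hypergeometric pathway enrichment, bipartite
    regulatory networks). A seeded synthetic-data module generates
    every input the pipeline consumes with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse,
    withr
Config/testthat/edition: 3
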