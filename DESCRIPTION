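Package: upstreamr
Title: Upstream Regulatory Analysis: Promoter Motif Enrichment, Composite
    Modules and Master-Regulator Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end "upstream analysis" pipeline for regulatory
    genomics: starting from a differential-expression table it scans promoter
    windows with position weight matrices using a Match-style normalized
    score, optimizes a per-matrix cutoff that maximizes the Yes/No
    site-frequency ratio under binomial significance (F-Match), searches for
    composite regulatory modules of co-localized sites with a genetic
    algorithm, and identifies candidate master regulators upstream of the
    implicated transcription factors in a directed signal-transduction
    network, with permutation significance and a positive-feedback filter.
    Includes a synthetic-data generator with planted ground truth for every
    stage, GSEA-style gene-set enrichment, hypergeometric overlap tests, and
    probit dose-response IC50 fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    limma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
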