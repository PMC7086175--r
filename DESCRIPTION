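Package: orgflux
Title: Gains and Losses of Organellar Targeting Signals Across Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A phylogenomic toolkit for charting the evolution of organellar
    protein targeting across gene families. Provides rule-based peroxisomal
    targeting-signal (PTS1/PTS2) classification, last-common-ancestor
    reconciliation of gene trees with a species tree, maximum-likelihood
    ancestral character estimation for binary targeting traits under two-state
    Markov (ER/ARD) models, stringent retention filters for calling gains and
    losses of targeting signals, mapping of changes onto species-tree branches,
    normalized molecular-rate comparisons with matched Monte Carlo resampling,
    duplication-association tests stratified by whole-genome versus single-gene
    origin, functional-term enrichment with Benjamini-Hochberg correction, and
    a duplication-loss gene-family simulator with full ground truth for
    end-to-end validation.
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
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
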