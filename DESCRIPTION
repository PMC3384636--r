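Package: episvm
Title: Sequence-Based Prediction of Linear B-Cell Epitopes from Antigen Chains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage sequence-based predictor of B-cell epitopes. Stage one
    scores sliding 20-residue windows of an antigen chain with a radial-basis
    support vector machine over a 198-dimensional feature encoding that
    combines predicted secondary structure, relative solvent accessibility,
    a renormalized dipeptide antigenicity scale, PSI-BLAST profile
    conservation, and substring similarity to libraries of known epitope and
    non-epitope fragments. Stage two aggregates overlapping window scores
    into per-residue epitope propensities (maximum, average, median, or
    distance-from-cutoff schemes). Includes biserial-correlation feature
    ranking with backward elimination under cross-validated Matthews
    correlation, evaluation metrics (ROC AUC, per-chain success rate), and a
    synthetic-data generator with planted class structure for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
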