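Package: moetox
Title: Multitask Mixture-of-Experts Models for Cardiotoxicity Endpoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multitask QSAR classification of cardiotoxicity-related endpoints
    from chemical structure with a single neural network. Implements SMILES
    standardization and label curation, molecular encoders (circular
    fingerprints and physicochemical descriptors) behind a pluggable registry,
    a sparse multitask label table with greedy per-task stratified splitting,
    a mixture-of-experts network whose gate weights multiple encoders on the
    probability simplex, masked class-balanced cross-entropy and
    uncertainty-weighted multitask losses, random-forest baselines, pooled and
    per-endpoint evaluation metrics, and a local-outlier-factor applicability
    domain with multi-encoder consensus. A synthetic-data generator with
    shared latent structure, controlled class imbalance and per-task
    missingness makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    ChemmineR,
    ChemmineOB,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
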