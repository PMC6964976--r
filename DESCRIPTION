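Package: dtimc
Title: Drug-Target Interaction Prediction by Multi-Graph Regularized
    Nuclear Norm Matrix Completion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-target interactions by completing the partially
    observed binary interaction matrix under a low-rank (nuclear norm)
    prior, regularized with combined graph Laplacians built from multiple
    drug-drug and target-target similarity measures (chemical structure,
    sequence, and four interaction-profile similarities: cosine,
    correlation, Hamming, Jaccard). Includes a singular value shrinkage
    solver for plain nuclear norm minimization, an ADMM solver with
    closed-form Sylvester updates for the multi-graph model, p-nearest
    neighbor graph sparsification, a graph-consistent synthetic data
    generator, and cross-validation under pair, novel-drug and
    novel-target hold-out settings with AUPR/AUC reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
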