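Package: mtsynergy
Title: Multi-Task Neural Prediction of Drug Combination Synergy and
    Monotherapy Sensitivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Jointly predicts anticancer drug-combination synergy (Loewe
    additivity scale, score and binary class) and monotherapy sensitivity
    (Relative Inhibition scale, score and binary class) from drug chemical
    features and cell-line gene expression with a multi-task feed-forward
    neural network. Drugs are featurized as hashed circular (Morgan-style)
    fingerprints plus filtered molecular descriptors; cell lines as z-scored
    top-variance log2(TPM+1) expression vectors; both are compressed by
    pre-trained autoencoders before entering a shared trunk with
    task-specific regression and softmax classification branches. Includes
    leakage-controlled dual five-fold cross-validation (leave-combination-out
    for synergy, leave-drug-out for sensitivity), grid search, evaluation
    metrics, a seeded synthetic-data generator with planted learnable
    signal, a YAML configuration layer, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
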