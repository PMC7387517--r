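Package: fmikeys
Title: Fine-Motor Impairment Severity from Smartphone Keystroke Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates Parkinsonian fine-motor impairment severity from
    smartphone touchscreen keystroke dynamics. Hold-time and flight-time
    sequences from natural typing sessions are turned into fixed-length
    two-channel inputs, encoded with a one-dimensional convolutional
    autoencoder pretrained on unlabelled typing data, and mapped to
    clinician-scale severity scores (UPDRS Part III items 22/23/31) by a
    fully-connected head fine-tuned under leave-one-subject-out
    cross-validation. Includes a synthetic-cohort simulator with a planted
    severity-to-dynamics mechanism, a screening evaluation battery (Pearson
    correlation, bootstrap ROC/AUC, sensitivity at fixed specificity),
    gradient saliency maps, and intra-day medication ON/OFF state analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
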