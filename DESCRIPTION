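Package: fragps
Title: Fragmentomic Cell-Free DNA Progression Score Assay Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for a qPCR cell-free DNA (cfDNA) fragmentomic
    assay that monitors treatment response in stage IV cancer patients. Covers
    simulation of synthetic cohorts and qPCR plates, eligibility and run-quality
    gating, standard-curve absolute quantification, derivation of fragmentomic
    variables (Frag1, Frag2, FragDiff, MMDiff) from short (>80 bp) and
    mid (>105 bp) amplicon concentrations at two blood draws, logistic model
    selection by AUC with leave-one-out cross-validation, bootstrap calibration
    of a Progression Score (0-100) cut-point to a target expected positive
    predictive value, and progression calls with contingency performance.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
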