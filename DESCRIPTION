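Package: histofeat
Title: Machine-Learned Histologic Features for Lymph Node Metastasis Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers machine-learned histologic features that add predictive
    signal for lymph-node metastasis beyond known clinicopathologic variables.
    Patch embedding vectors are clustered with k-means, each case is summarised
    by the fraction of its patches falling in each cluster (the cluster
    quantitation vector), and clusters are selected greedily by training AUROC
    with the baseline clinicopathologic covariates held in a logistic model
    throughout. Evaluation covers nested-model likelihood-ratio tests,
    multivariable odds ratios, bootstrap confidence intervals for AUROC gains,
    operating-point metrics, batch-confound checks, and Kaplan-Meier risk
    stratification of disease-specific survival. A synthetic-cohort generator
    with planted cluster signal, covariate coupling, batch shifts and survival
    outcomes makes the whole pipeline testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
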