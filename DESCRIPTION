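Package: nichestrat
Title: Spatial Cell Niches and Niche-Based Survival Risk Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for spatial single-cell phenomics of multiplex
    immunofluorescence tissue-microarray cohorts. From per-cell boolean
    marker calls the package derives cell phenotypes via an editable
    gating table, discovers spatial cell niches by clustering 34 um
    neighborhood marker compositions with mini-batch k-means, matches
    independently derived niche sets across tumor subtypes with partial
    optimal transport on chi-squared phenotype distances, and builds a
    multiple-instance survival model (censored-data mRMR feature
    selection, Yeo-Johnson normalization, ridge Cox regression,
    max-pooled patient risks) evaluated against clinical staging with
    concordance indices, Kaplan-Meier/log-rank analyses and bootstrap
    comparisons. A synthetic tumor-microenvironment cohort generator
    with planted niche structure and proportional-hazards survival
    makes every stage testable without access to restricted cohort
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    Matrix,
    survival,
    glmnet,
    clue,
    uwot
Suggests:
    testthat (>= 3.0.0),
    mclust,
    car,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
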