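Package: symptomnet
Title: Symptom Profile Enumeration and Partial-Correlation Network Analysis
    for Ordinal Questionnaires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the heterogeneity of questionnaire-defined
    syndromes such as PHQ-9 depression. Enumerates all theoretically possible
    dichotomized symptom profiles under a diagnostic rule (severity threshold
    or DSM-style minimum-count rule), matches respondents to profiles, and
    estimates within-profile symptom networks as Gaussian graphical models
    with EBIC-selected graphical-lasso regularization or a significance-
    thresholded non-regularized estimator. Includes strength centrality,
    Fruchterman-Reingold layouts, nonparametric bootstrap edge-accuracy
    intervals, the case-dropping correlation-stability (CS) coefficient, and
    a latent-Gaussian synthetic cohort generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    MASS,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
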