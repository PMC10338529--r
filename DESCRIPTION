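Package: gaitsig
Title: Subject and Footwear Signatures in Ground Reaction Force Curves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation, preprocessing, classification and explanation of
    tri-axial ground reaction force (GRF) recordings from running.  Provides a
    parametric generator for stance-phase GRF cohorts with subject-specific
    signatures and footwear-specific effects; zero-phase Butterworth
    filtering, threshold-based stance detection, 101-point time
    normalisation and body-weight scaling; one-vs-rest linear support vector
    classification (L2-regularised L2-loss, dual coordinate descent) under
    nested task-stratified cross-validation; layer-wise relevance propagation
    for linear models; and time-continuous (permutation SPM ANOVA) as well as
    time-discrete (Kruskal-Wallis with Dwass-Steel-Critchlow-Fligner
    post-hoc) statistical evaluation of footwear effects.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    yaml
Config/testthat/edition: 3
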