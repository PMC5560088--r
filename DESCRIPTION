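Package: hemitopo
Title: Contralesional Hemispheric Connectivity Topology and Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of hemispheric resting-state functional
    connectivity in two-group cohort designs (e.g. slow- versus fast-growing
    glioma). Builds per-subject Fisher-z ROI connectivity matrices from
    denoised time series, classifies subjects from the upper-triangle feature
    space with Kendall-tau consensus feature selection, a linear support
    vector machine under leave-one-out cross-validation and a permutation
    null, and characterizes weighted network topology (global and local
    efficiency normalized against degree-preserving rewired null networks,
    weighted modularity, intra- and intermodular connectivity) integrated
    over a proportional-sparsity range, with permutation group tests, false
    discovery rate correction, and covariate-adjusted ANOVA. Includes a
    synthetic cohort generator with block-modular correlation structure for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    igraph,
    withr
Config/testthat/edition: 3
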