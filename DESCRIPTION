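Package: stagenet
Title: Stage-Dependent Brain Covariance Networks and Memory
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Individual-level analysis of structural (grey-matter volume) and
    metabolic (FDG PET) brain covariance networks across the Alzheimer's
    disease continuum. Defines seed regions from nuisance-adjusted permutation
    group contrasts with threshold-free cluster enhancement and family-wise
    error control; derives per-participant network scores by seed partial
    least squares (correlation vector, singular value decomposition,
    permutation tests, bootstrap ratios); stratifies participants by CSF
    amyloid/tau pathology and orders them along a clinical pseudo-stage; and
    models stage-varying network-memory associations with a sparse
    varying-coefficient regression (B-spline coefficient functions under a
    group lasso or ridge penalty, cross-validated tuning, repeated-selection
    stability and permutation specificity). Ships a synthetic-cohort
    generator with planted covariance networks and known coefficient curves
    so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
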