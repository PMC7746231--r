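Package: protex
Title: Prototype and Exemplar Models of Category Learning with Model-Based fMRI Regressors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how people represent novel categories: builds
    binary-feature stimulus spaces with category prototypes and Hamming-distance
    structured training and generalization test sets, computes prototype and
    exemplar (generalized context model) similarities with per-feature attention
    weights and a sensitivity parameter, fits both models to trial-by-trial
    classification choices by maximum likelihood, classifies each subject's
    strategy against a permutation null, summarises behavioral typicality
    gradients and old-item advantages, and constructs model-based parametric
    regressors, gamma-HRF design matrices and ROI effect sizes for fMRI
    analysis. Includes synthetic observers and synthetic BOLD generators so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
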