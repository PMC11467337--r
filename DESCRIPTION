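Package: holoblast
Title: Holotomography Morphometry and Deep-Learning Screening of NPM1-Mutant Myeloblasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for label-free analysis of myeloblast refractive-index (RI)
    tomograms in acute myeloid leukemia. Provides a seeded generator of
    synthetic 3D myeloblast phantoms with class-conditional subcellular
    statistics for the NPM1 wild-type and mutant genotypes, rule-based
    subcellular segmentation, morphometric parameter extraction (volume,
    iso-surface area, sphericity, mean RI, dry mass via the specific
    refractive increment), Mann-Whitney group comparisons with significance
    tiers, a configurable 3D tail-body-head convolutional network for
    single-cell genotype prediction, and patient-level mutation screening by
    positive-prediction-ratio ROC analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    rhdf5,
    tiff
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
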