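Package: ctpheno
Title: CT-Derived Heart and Lung Phenotypes and Their Quantitative Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for turning stacks of thoracic CT slices into heart- and
    lung-volume phenotypes and for the genetic analysis of those phenotypes in
    pedigreed populations. Includes a synthetic phantom generator with analytic
    ground truth, a slice classifier and three-level changepoint smoother that
    locate the chest as one contiguous slice interval, a compact CPU U-net
    trained with a soft Dice loss for heart/lung segmentation with
    Hounsfield-unit thresholding of lung air, voxel-counting volumetry,
    descriptive and allometric (power-law) regressions of organ volume on body
    weight, and a pedigree BLUP animal-model toolkit: numerator-relationship
    inverses with unknown-parent groups, Meuwissen-Luo inbreeding, Henderson's
    mixed-model equations, EM/average-information REML for univariate and
    bivariate models, heritabilities, genetic correlations and genetic trends.
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
    Matrix,
    methods,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
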