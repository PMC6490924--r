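Package: cmtradeoff
Title: Noisy-Observer Modelling of Color-Material Trade-Off in Object Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for modelling two-alternative forced-choice object
    selection when test objects vary along two perceptual dimensions
    (color and material). Implements a two-dimensional noisy-observer
    model in which each stimulus is represented by a bivariate Gaussian
    in a latent perceptual space and selections follow weighted
    target-test distances (Euclidean or city-block), Monte-Carlo
    construction of gridded choice-probability lookup tables with cubic
    interpolation, maximum-likelihood fitting of four positional-mapping
    variants, a preregistration-style cross-validated model-selection ladder,
    a QUEST+ adaptive trial-placement engine, a full session simulator
    reproducing the experimental block design, and post-fit analyses
    (bootstrap confidence intervals, color-material trade-off functions,
    slope ratios, and parameter-recovery studies).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
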