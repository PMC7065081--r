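Package: floramorph
Title: 3D Geometric Morphometrics, Modularity and Macroevolution of Flower Shape
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of 3D floral shape across a
    clade: generalized Procrustes alignment of landmark configurations,
    shape principal components, eigenvalue-variance integration, allometric
    regression with permutation tests, RV-coefficient modularity tests
    against random-partition null distributions, random-forest pollination
    syndrome classification, equal-rates Markov ancestral state
    reconstruction with stochastic character mapping, regime-dependent
    Brownian-motion and Ornstein-Uhlenbeck trait-evolution model selection
    by AICc, penalized-likelihood multivariate model fitting with GIC,
    ancestral shape reconstruction and thin-plate-spline warping.  Includes
    a synthetic-data generator with planted modular covariance, allometry
    and regime histories for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    withr,
    Matrix,
    optparse
Config/testthat/edition: 3
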