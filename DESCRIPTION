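Package: partkrig
Title: Partitioned Spatial Linear Models for Large Point-Referenced Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits the spatial linear model to large point-referenced data
    sets by spatially indexing observations into blocks. Covariance
    parameters (partial sill, nugget, range) are estimated by restricted
    maximum likelihood on a block-diagonal working covariance matrix, and
    fixed effects by a pooled generalized-least-squares estimator whose
    covariance matrix is corrected exactly for cross-block correlation.
    Point prediction uses nearest-neighbour universal kriging under a single
    global coefficient estimate, and areal (block) means are predicted by
    averaging point predictions over a dense grid with an exact streamed
    prediction variance. Includes two synthetic surface generators
    (Cholesky-based Gaussian random fields and sums of random sine waves)
    and a simulation harness for coverage and prediction-error studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
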