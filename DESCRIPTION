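Package: grnshot
Title: Gene Regulatory Network Reconstruction Under One-Shot and
    Multi-Shot Time-Series Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference framework for studying how the design
    of time-series expression experiments (one-shot versus multi-shot
    sampling, numbers of conditions, replicates and sampling times) affects
    gene regulatory network reconstruction.  Provides a Gaussian linear
    dynamic model with explicit condition, biological and technical
    variance components together with its exact sample covariances; a
    generalized likelihood-ratio sign estimator for single-gene
    autoregulation; a best-subset lagged regression estimator with a
    Granger F-test pruning stage (BSLR); ternary signed-structure loss
    functions with random-guess baselines; a stochastic differential
    equation model of the Arabidopsis circadian clock with
    condition-coupled multiplicative noise; and factorial experiment
    drivers that reproduce the associated simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
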