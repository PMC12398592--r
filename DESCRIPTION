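Package: udefit
Title: Training Universal Differential Equations for Systems Biology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and training universal differential equations
    (UDEs): mechanistic ordinary differential equation models whose right-hand
    side or observable mapping is augmented additively with feed-forward neural
    networks. Ships the Ruoff yeast glycolysis oscillator and the Boehm STAT5
    dimerisation model together with their UDE variants, a bounded tanh
    parameter transform, maximum-likelihood objectives with jointly estimated
    observation noise, weight-decay regularisation, forward sensitivity
    gradients (with a compiled sensitivity integrator for the glycolysis
    problems), ADAM-then-BFGS single-start training with early stopping,
    Latin-hypercube multi-start orchestration over parameters and
    hyperparameters, synthetic data generation over noise and sparsity grids,
    and evaluation metrics (NMAE, AIC/BIC, chi-squared confidence regions,
    oscillation recovery, parameter and noise recovery).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
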