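Package: apuq
Title: Uncertainty Quantification and Sensitivity Analysis for a Canine
    Epicardial Action Potential Model
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A 36-parameter Hodgkin-Huxley-style canine epicardial action
    potential model (six ionic currents, seven state variables) together
    with a complete uncertainty-quantification and global-sensitivity
    workflow: hyper-parameter-controlled normal/lognormal parameter
    distributions, Monte Carlo propagation with convergence checking,
    Sobol variance-based indices and Morris elementary-effects screening,
    action-potential behavior classification, Monte Carlo filtering with
    Kolmogorov-Smirnov influence statistics, and a 1D monodomain strand
    solver for conduction velocity. Simulation kernels are implemented in
    C++ via Rcpp; results are returned as tibbles with tidy(), glance()
    and autoplot() methods.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
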