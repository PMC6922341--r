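Package: setpointr
Title: Set-Point Detection and Topology Recovery for Nonlinear Dynamical Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers the topology of nonlinear dynamical systems from
    multivariate time series by fitting quantile regression forests to
    difference-equation outcomes. Grid coordinates whose quantile
    pseudo-confidence interval of predicted change contains zero are flagged
    as set points, and the local dynamics around each set point (attraction,
    repulsion, transience, cycling) are classified by directional probes and
    Jacobian eigenvalue analysis. Includes a stochastic cusp-catastrophe
    simulator, a maximum-likelihood cusp density fit with Cobb's pseudo
    R-squared for quantifying recovery, a Monte Carlo driver, and surrogate
    generators for point-attractor and limit-cycle regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    purrr,
    lattice,
    jsonlite,
    optparse
Config/testthat/edition: 3
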