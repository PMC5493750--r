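Package: lanesim
Title: Simulation and Fluctuating Hydrodynamics of Binary Active Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying lane formation and critical mingling in
    two-dimensional mixtures of self-propelled particles driven toward
    opposite directions. Provides a fast torque-coupled microscopic
    simulator with periodic boundaries, order-parameter and
    pair-correlation observables, orchestration and fitting of
    repulsion-strength sweeps across the laning transition, deterministic
    two-body scattering experiments, and the linearized two-species
    fluctuating-hydrodynamic theory with its anisotropic non-analytic
    structure factor and a stochastic spectral integrator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    mclust,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
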