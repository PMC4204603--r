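Package: satdyn
Title: Attractor-Network Dynamics of the Speed-Accuracy Trade-Off
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and dynamical-systems analysis of a reduced
    two-population attractor model of two-choice perceptual decision making.
    A spatially non-selective background current trades decision speed
    against accuracy; the package simulates coherence-dependent random-dot
    motion trials with Ornstein-Uhlenbeck input noise, fits psychometric
    (Weibull) and chronometric summaries, performs the threshold-compensation
    experiment, computes phase-plane structure (fixed points, saddle
    eigenstructure, stable and unstable manifolds, effective integration
    time constant), and runs ideal-observer (ROC) analyses of the simulated
    population rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
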