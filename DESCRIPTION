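Package: brainturb
Title: Turbulence-Based Characterisation of Whole-Brain Dynamical States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-free and model-based tools for distinguishing brain states
    from parcellated BOLD time series through the lens of turbulence. Computes
    local Kuramoto order parameter fields over a grid of spatial scales,
    amplitude turbulence, information cascade flow and cascade, spatial
    transfer correlation and node-level metastability; fits a coupled
    Stuart-Landau (Hopf) whole-brain model on an exponential-distance-rule
    connectome by matching functional connectivity as a function of Euclidean
    distance; applies in-silico perturbation protocols (periodic forcing and
    bifurcation-parameter shifts) to fitted models and reports susceptibility
    and information encoding capability; and runs rank-based group comparisons
    with false-discovery-rate control. Includes a synthetic-cohort generator
    with known ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    deSolve,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
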