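Package: surfhop
Title: Fewest-Switches Surface Hopping with Projected-Force-Momentum
    Decoherence on Model Hamiltonians
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Nonadiabatic molecular dynamics on analytic diabatic model
    Hamiltonians. Implements fewest-switches trajectory surface hopping with
    local-diabatization electronic propagation and a family of electronic
    decoherence corrections: the energy-based correction (EDC), the
    forces-and-momenta (FM) rate for one-dimensional systems, its
    trajectory-velocity-projected multidimensional generalization (PFM), and
    the momentum-injection variants (FMi/PFMi) that cure the momentum history
    problem of inactive-state auxiliary momenta. Ships an exact one-dimensional
    multi-state split-operator quantum propagator as reference, Wigner
    phase-space sampling of initial conditions (including initial coherent
    electronic superpositions), ensemble energy-drift filtering with
    stochastic rebalancing, and internal-consistency diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
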