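Package: mguq
Title: Uncertainty Quantification for Magnesium Implant Biodegradation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow for quantifying uncertainty in computational models of
    the biodegradation of magnesium-based bone implants. Provides three
    deterministic degradation simulators (a quasi-1D moving-interface model of
    pure-Mg corrosion, a reaction-diffusion model of precipitate formation in
    the porous degradation layer, and a diffusion-limited volume-loss model for
    alloy implants), one-shot and adaptive design of computer experiments,
    three surrogate families (Kriging with a Matern 5/2 kernel, sparse
    polynomial chaos expansions on a hyperbolic index set, and polynomial chaos
    Kriging), leave-one-out and NRMSE validation, surrogate-based parameter
    calibration, uncertainty propagation, and variance-based Sobol sensitivity
    analysis (analytic for polynomial chaos, pick-freeze Monte Carlo
    otherwise). Synthetic calibration datasets with known ground truth make the
    full workflow testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    lhs,
    methods,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    pracma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
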