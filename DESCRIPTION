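Package: halokin
Title: Transient Kinetics of Flavin-Dependent Halogenase Catalysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of the pre-steady-state kinetics of
    flavin-dependent halogenases (FDHs) such as tryptophan 6-halogenase (Thal).
    Implements the branched mass-action reaction scheme linking reduced-flavin
    binding, C4a-hydroperoxyflavin formation, hypohalous-acid (HOX) generation,
    uncoupled hydrogen-peroxide elimination, HOX capture versus leakage, and
    isomerization to a dead-end inactive complex; maps species concentrations to
    stopped-flow absorbance and fluorescence observables; fits multi-exponential
    traces, hyperbolic halide-saturation (Kd, k) datasets and inactivation
    amplitude series; computes branching and coupling budgets; and checks
    transition-state-theory rate ordering against measured rate constants.
    A seeded synthetic-data generator emulates the stopped-flow, double-mixing
    and rapid-quench-flow experiments for parameter-recovery studies.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
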