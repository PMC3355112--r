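Package: kvgating
Title: Markov-Model Simulation and Analysis of Kv Channel Gating Currents
Version: 0.1.0
Authors@R:
    person("kvgating", "maintainers", email = "kvgating@example.org",
           role = c("aut", "cre"))
Description: Kinetic (Q-matrix) modelling of voltage-sensor gating in
    homotetrameric Kv2.1-like channels and 3:1 heterotetramers carrying one
    electrically silent subunit, together with a complete gating-current
    analysis pipeline: simulation of ON-gating and ionic currents under
    step-voltage protocols, stochastic (Gillespie) single-channel simulation,
    Q-V construction with single and double Boltzmann fitting, apparent
    gating-charge estimation from Boltzmann slopes, exponential decay fitting
    with weighted time constants, trace-crossing detection, Cole-Moore delay
    measurement, G-V curves from peak ionic currents, and a synthetic
    patch-clamp recording generator (noise, Bessel-type filtering, leak and
    capacitance artifacts, P/8 subtraction, mixed channel populations) with
    ground truth attached for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
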