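Package: slowbindr
Title: Slow-Binding Covalent-Reversible Enzyme Inhibition Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of slow-binding, covalent-reversible
    enzyme inhibition kinetics as used to characterize peptidyl-ketoamide
    inhibitors of rhomboid intramembrane proteases. Provides closed-form and
    ODE simulation of inhibited-protease progress curves, nonlinear fitting
    of biphasic progress curves to extract initial and steady-state rates
    (vi, vs) and the onset-of-inhibition rate constant kobs, linear and
    hyperbolic analysis of the kobs-inhibitor dependence yielding kon, koff
    and the apparent inhibitory constant Kiapp, global Michaelis-curve
    fitting with statistical selection among competitive, noncompetitive,
    uncompetitive and mixed inhibition models, apparent-IC50 dose-response
    fitting, jump-dilution reversibility analysis, and quantification
    helpers for immunoblot conversion assays and activity-based-probe
    competition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
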