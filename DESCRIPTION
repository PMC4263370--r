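Package: nssnet
Title: Normalized Steady-State Metabolic-Regulatory Network Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build multi-compartment kinetic metabolic networks with
    transcriptional and post-translational regulation, parameterize them at a
    normalized steady state from reaction reversibility (r), branch flux
    fractions (f), bound/free enzyme ratios (w) and influxes (phi) instead of
    measured kinetic constants, simulate perturbations with a stiff ODE
    solver, and run flux-distribution sensitivity (metabolic control)
    analysis with impact classification and tolerance-range detection.
    Ships toy fixtures with analytic oracles, a reduced liver-adipose-blood
    network, qualitative validation scenarios, a line-oriented model
    definition format and a restricted Modelica-subset importer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
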