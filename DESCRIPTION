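Package: fenestra
Title: Logic-Based ODE Modeling of Glomerular Endothelial Fenestration
    Dynamics in Diabetic Kidney Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a multicellular logic-based ordinary differential
    equation (LBODE) signaling network coupling glucose-driven macrophage
    activation to glomerular endothelial cell (GEC) cytoskeletal signaling,
    and couples the network to ordinary differential equations for the
    number and diameter of GEC fenestrations. Provides a dynamic
    hyperglycemic glucose stimulus with a seeded virtual mouse population,
    staged multi-start nonlinear least-squares calibration of the
    structural parameters with Latin hypercube starts, resampling-based
    uncertainty propagation with equal-tail credible bands, local
    sensitivity screening of species knockdowns and reaction inhibitions,
    and in silico intervention protocols (glucose control, chemical-agent
    knockouts, timed partial knockdowns).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    lhs,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
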