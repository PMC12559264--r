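Package: fontansim
Title: Lumped-Parameter Simulation of Fontan Circulation with Collateral
    Vessels
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Closed-loop zero-dimensional (lumped-parameter) simulation of
    the total cavopulmonary connection (Fontan) circulation.  A
    time-varying elastance single ventricle and atrium drive a Windkessel
    vascular network with parallel systemic beds, a passive Fontan
    pathway, and optional collateral shunts (venovenous collaterals,
    aortopulmonary collaterals, and a conduit fenestration).  A
    Fick-principle oxygen layer solves the node-level saturation mixing
    balance on beat-averaged flows, predicting arterial and central
    venous oxygen saturations.  Tools are included for pulmonary- and
    systemic-resistance sweeps, dobutamine dose-response simulation,
    pressure-volume loop analysis (EF, Ees/Ea, SW/PVA), registry
    calibration, and fixture generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    igraph,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
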