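Package: hydrolysim
Title: Semi-Mechanistic Kinetics of Enzymatic Hydrolysis of Pretreated
    Sugarcane Bagasse
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and parameter estimation for a semi-mechanistic
    kinetic model of batch enzymatic saccharification of pretreated
    lignocellulose (hydrothermal and organosolv sugarcane bagasse). The
    model couples Michaelis-Menten rate laws with competitive product
    inhibition, Langmuir adsorption of cellulase on the substrate and on
    lignin, a lignin-dependent surface-decay law, and xylanase-catalysed
    xylan hydrolysis. Includes a fixed-grid fourth-order Runge-Kutta
    integrator (compiled), a Pikaia-style real-coded genetic algorithm
    for parameter estimation, Levenberg-Marquardt fitting of the
    surface-decay Hill law, Plackett-Burman time-resolved parameter
    sensitivity screening, and a synthetic-data generator emulating the
    batch assay design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    grDevices,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
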