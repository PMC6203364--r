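Package: tumorca
Title: Hybrid 3D Cellular-Automaton Model of Invasive Tumor Growth under
    Chemotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates avascular invasive solid-tumor growth under
    chemotherapy with a hybrid multiscale model: a two-compartment
    physiologically based pharmacokinetic (PBPK) model that motivates
    time-dependent boundary conditions, an explicit finite-difference
    solver for drug diffusion-reaction with Michaelis-Menten uptake and
    heterogeneous diffusivity, and a cellular automaton on a Voronoi
    tessellation of a random hard-sphere packing with proliferative,
    quiescent, necrotic and invasive phenotypes in heterogeneous
    extracellular matrix. A quasi-parallel driver interleaves drug
    transport sub-steps with cohort-wise cell division within each cell
    cycle. Includes experiment presets for constant, periodic and
    region-restricted dosing schedules and summary growth metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    deSolve,
    jsonlite
Config/testthat/edition: 3
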