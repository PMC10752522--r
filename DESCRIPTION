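Package: splenosim
Title: Mesoscale Simulation of Sickle Red Blood Cell Retention by Splenic Macrophages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained simulation toolkit for quantifying the retention of
    sickle red blood cells (RBCs) by wall-adhered macrophages under shear flow.
    Provides triangulated-mesh generators for four RBC morphologies with exact
    surface-area and volume control, a wormlike-chain spring-network membrane
    model with bending and area/volume constraints, a dissipative particle
    dynamics (DPD) solvent with Couette boundary conditions, a stochastic
    receptor-ligand bond model with oxygenation-dependent kinetics, Morse-potential
    RBC aggregation, and a fast two-dimensional reduced mode used to run virtual
    assays: detachment calibration, retention versus oxygenation, aggregation,
    hematocrit, flow velocity, and cell shape.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
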