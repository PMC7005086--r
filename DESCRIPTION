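Package: cellmech
Title: Deformable and Center-Based Cell Models for Growing Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of cell and tissue mechanics at two
    resolutions. Cells are represented either as triangulated viscoelastic
    surfaces (deformable cell model, DCM) with cortex in-plane elasticity,
    bending, volume pressure and membrane-area conservation, interacting
    through Maugis-Dugdale adhesive contact integrated over projected
    triangle pairs, or as sticky elastic spheres (center-based model, CBM)
    with Johnson-Kendall-Roberts forces and a packing-dependent stiffness
    correction calibrated from DCM compression runs. Overdamped dynamics
    with friction coupling, cell growth, an envelope-constrained division
    algorithm, and virtual experiments (optical stretcher, pull-off,
    compression calibration, spheroid and monolayer growth, liver-lobule
    regeneration) are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
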