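Package: planareit
Title: Three-Dimensional Difference Imaging for Planar-Array Electrical
    Impedance Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and reconstruction pipeline for bladder-volume
    monitoring with a planar 8x8 electrode array: complete-electrode-model
    finite-element forward solver on tetrahedral tank meshes, adjoint
    sensitivity (Jacobian) computation, linearized difference imaging with
    Tikhonov, NOSER and combined regularization, steplike-edge boundary
    surface extraction by Laplacian zero-crossing marching tetrahedra, and
    voxel-based volume and position quantification of the detected anomaly.
    Includes a synthetic cuboid-phantom generator emulating the
    saline-in-agar feasibility experiment and a command-line pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
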