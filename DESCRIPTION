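Package: phantomforge
Title: Ground-Truth Phantom Production for Molecular Radiotherapy Dosimetry
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for producing the ground truth behind 3D-printed
    anthropomorphic phantom studies in molecular radiotherapy dosimetry.
    Converts labelled voxel phantoms into smoothed, watertight, printable
    hollow organ shells (surface extraction, Laplacian smoothing, shell
    extrusion, overlap resolution, STL export); solves a linear compartmental
    pharmacokinetic model for Lu-177 DOTATATE by fixed-step fourth-order
    Runge-Kutta to obtain per-compartment activity-concentration schedules at
    clinical timepoints; plans traceable radioactive dispensing with
    gravimetric volume determination and first-order uncertainty propagation
    in concise parenthesis notation; and verifies achieved against modelled
    activity concentrations with fill-fraction and deviation reports plus
    voxel activity-map export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
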