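Package: cabvort
Title: Vortex and Wall Shear Stress Analysis for Carotid Bifurcation Hemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying vortical structures in pulsatile flow through the
    carotid artery bifurcation. Builds watertight parametric bifurcation surface
    meshes for healthy and atherosclerosis-predisposed anatomies, models the
    pulsatile common-carotid inflow waveform with Reynolds-number calibration and
    resistive outlet boundary conditions, and post-processes time-resolved
    velocity/pressure fields: lambda2 vortex identification and region tracking,
    instantaneous and time-averaged wall shear stress, pressure-minimum vortex-core
    trajectories in a sinus-anchored frame, secondary-flow decomposition on
    centerline-perpendicular planes, and axial pressure-gradient analysis. Includes
    analytic synthetic-flow generators (Poiseuille, Womersley, Lamb-Oseen,
    Biot-Savart hairpin filaments, advecting pressure wells) carrying machine-
    readable ground truth for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
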