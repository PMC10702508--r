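Package: sectmap
Title: Single-Energy CT Tissue Parametrization for Proton Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise estimation of mass density and proton relative
    stopping power (RSP) from single-energy CT (SECT) Hounsfield units.
    Implements the physics-based stoichiometric calibration (parametric
    attenuation model with fitted scanner-spectrum coefficients and the
    Bethe equation), piecewise dual-energy CT (DECT) empirical reference
    models, and three supervised deep voxel regressors (a single-hidden-layer
    ANN, a 1D fully convolutional network and a 1D residual network) trained
    on electron-density-phantom scans. A virtual phantom simulator renders
    ground-truthed SECT volumes of electron-density and anthropomorphic
    torso phantoms so the full train/calibrate/evaluate workflow runs
    without access to scanner data, and APE/MAPE evaluation machinery
    compares all models per tissue region.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
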