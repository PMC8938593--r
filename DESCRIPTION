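Package: y90ct
Title: CT-Based Voxel Dosimetry for Yttrium-90 Radioembolization with
    Radiopaque Microspheres
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for post-treatment dosimetry of yttrium-90
    radioembolization using CT imaging of radiopaque microspheres.
    Fits Hounsfield-unit versus microsphere-concentration calibration
    curves from a multi-post phantom, converts CT volumes to microsphere
    concentration and voxelized activity, generates dose-voxel kernels by
    reduced Monte-Carlo beta transport in water, performs FFT convolution
    dosimetry and MIRD mono-compartment reference doses, computes
    dose-volume metrics (median, mean, maximum dose, COV, D70, cumulative
    DVHs), detectability limits (LOB/LOD/MDA), and cross-modality
    agreement statistics (linear regression, Bland-Altman, one-way
    ANOVA). Includes a synthetic calibration-phantom and virtual-subject
    generator so the full pipeline is testable without image downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
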