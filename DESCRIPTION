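Package: perfph
Title: pH-Weighted Mapping of Glioblastoma from DSC-MRI Perfusion Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline that estimates voxel-wise tumor
    acidity maps in glioblastoma from dynamic susceptibility contrast (DSC)
    perfusion MRI. The package quantifies amine CEST MTR-asymmetry at 3 ppm
    from z-spectral acquisitions (including B0 inhomogeneity estimation via
    K-means clustering and Lorentzian fitting), applies temporal principal
    component analysis to aligned and normalized perfusion signal-time curves,
    and predicts MTR-asymmetry from the principal-component scores with
    Gaussian-kernel support vector regression under leave-one-subject-out
    cross-validation. A digital-phantom generator with known latent
    hemodynamics and ground-truth acidity makes every stage testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    e1071,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
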