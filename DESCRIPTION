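Package: MarkerVis
Title: Passive Paramagnetic Marker Visibility and Detection in Interventional MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of passive paramagnetic marker
    susceptibility artifacts on 2-D magnitude MRI frames of a pulsatile
    flow phantom at 3 T. Provides a synthetic phantom generator (point-dipole
    off-resonance with intravoxel dephasing under GRE- and bSSFP-like
    contrast, pulsatile blood signal, Rician noise), the artifact
    quantification pipeline (frame discard, blood-intensity frame pairing,
    reference-minus-marker subtraction, agar mean+3*SD thresholding,
    artifact segmentation, mean artifact width and contrast-to-noise
    ratios), a Gaussian-heatmap U-Net marker detector with threshold-sweep
    true/false-positive evaluation, exact Wilcoxon signed-rank statistics
    with median/IQR reporting, and NIfTI + JSON series I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
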