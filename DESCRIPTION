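Package: aortaflex
Title: Ascending-Aorta Elasticity from Cine Image Segmentation and Biaxial Tensile Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies elastic properties of the ascending aorta from
    time-resolved (cine) cross-sectional image sequences. Provides a
    U-Net semantic segmentation model with instance normalization trained
    with Dice loss, computation of global and quadrant-local aortic
    compliance and wall strain from segmented lumen masks and blood
    pressures, ex-vivo biaxial tensile stress-strain analysis with tangent
    Young's modulus (maximum and physiological), segmentation evaluation
    metrics (Dice, IoU, Hausdorff distance, precision, recall), and
    Pearson/Bland-Altman agreement statistics. A synthetic pulsating-vessel
    phantom generator with exact analytic ground truth makes every stage of
    the pipeline testable without patient data.
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
    grDevices,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png
Config/testthat/edition: 3
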