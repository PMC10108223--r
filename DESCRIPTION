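Package: gliaquant
Title: 3D Morphometry of Radial Glia in Calibrated Fluorescence Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A scriptable re-implementation of a radial-glia morphology
    workflow for 3D fluorescence microscopy: calibrated TIFF stack and
    ImageJ-style ROI input/output, quantitative image-quality assessment
    (SNR/CNR, z-axis signal decay), geometric standardization of retinal
    stacks to a common apicobasal frame via line-ROI-driven subregion
    extraction, Richardson-Lucy deconvolution with a theoretical
    diffraction point spread function, a suite of histogram and hysteresis
    segmentation methods, and 3D quantification of binary masks (volume,
    coverage, surface, Euclidean-distance-transform thickness, thinning
    skeleton topology and apicobasal texture profiles).  Ships a synthetic
    phantom generator with analytic ground truth so every stage is testable
    without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
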