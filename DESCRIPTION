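Package: ioimap
Title: Fourier Activity Mapping and Segmentation for Intraoperative Optical Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for stimulation-locked intraoperative optical
    imaging (IOI) of the exposed cortex. Computes pixelwise spectral activity
    maps (stimulation-frequency power relative to very-low-frequency
    vasomotion power), segments activation areas by mean-plus-SD thresholding
    with small-component removal and largest-component selection, and
    quantifies agreement with reference (e.g. fMRI-derived) masks through
    DICE coefficients, region-restricted quartile statistics and topographic
    label maps. Includes a seeded synthetic cortical-reflectance simulator
    with ground-truth masks so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    grDevices,
    tools,
    utils,
    tiff,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
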