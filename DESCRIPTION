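Package: lfaquant
Title: Quantitative Readout of Lateral Flow Assay Strip Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Densitometric quantification of gold-nanoparticle lateral flow
    assay (LFA) strips from smartphone or benchtop-imager photographs.
    Extracts flow-axis intensity profiles, performs baseline correction,
    detects and integrates the test and control lines, computes normalized
    (cl/tl) and standardized (tl/cl) band-intensity ratios, fits linear
    calibration models of ratio versus analyte concentration with replicate
    statistics and inverse prediction, and derives limits of blank,
    detection and quantification (LOB/LOD/LOQ) by two blank-statistic
    methods on both the intensity and the concentration scale. Includes a
    seeded synthetic strip-image generator with exact ground truth so the
    whole pipeline is testable without laboratory data, a batch pipeline
    with CSV outputs and self-contained analysis reports, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff,
    withr
Config/testthat/edition: 3
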