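Package: canopycolor
Title: Colour-Checker Anchored Colour Correction for Field Phenotyping Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for consistent canopy colour phenotyping from ground-based
    field images taken under varying illumination. Locates a 24-tile colour
    checker in each plot image, fits a per-channel quadratic colour-correction
    model in CIELAB by least squares, detects the phenotyping vehicle's rails
    to mask the region of interest, segments plant pixels with a support
    vector machine trained on k-means cluster centres in CIELUV chromaticity,
    extracts corrected mean canopy colour time series, and predicts NDVI from
    canopy colour. Includes a fully ground-truthed synthetic scene generator
    so every pipeline stage can be validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    tools,
    png,
    jsonlite,
    yaml,
    e1071
Suggests:
    tiff,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
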