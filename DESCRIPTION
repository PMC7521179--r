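Package: organoidscreen
Title: Fluorescence Scoring and Selection of Stem-Cell-Derived Organoids in Well Plates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated grading of fluorescent-reporter expression in
    stem-cell-derived organoids imaged one-per-well in 96-well plates.
    Implements a pixel pipeline (central-rectangle background estimation,
    background subtraction, linear contrast adjustment, thresholding and
    positive-pixel counting), empirical-CDF calibration of a score threshold
    from manually labeled negative organoids, positive-organoid
    classification with plate layouts, half-plate edge-effect comparisons,
    and Mann-Whitney comparisons of per-plate positive fractions between
    experimental groups. A synthetic well-image generator with exact pixel
    ground truth supports end-to-end validation, and a command-line
    interface ties the steps into a screening workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tiff,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
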