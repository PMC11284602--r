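Package: strawpheno
Title: Image-Based Strawberry Phenotyping with Fiducial-Marker Calibration
Version: 0.1.0
Authors@R:
    person("Maintainer", "Packages", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measurement pipeline for image-based strawberry phenotyping.
    A square fiducial marker of known physical side length is located in an
    RGB image and a plane homography converts pixel coordinates to metric
    coordinates, so that six phenotypic traits (crown diameter, plant
    height, petiole length, leaf area/length/width, flower area, fruit
    area) can be extracted in physical units from detections and
    segmentation masks supplied by pluggable backends.  Includes a
    fruit-area to fresh-weight regression, validation statistics (Pearson
    correlation, paired t-tests, detection frequency), one-dimensional
    k-means size clustering with ANOVA and Tukey HSD compact letter
    displays, readers for both VGG Image Annotator dialects (v1 CSV and
    v2 JSON), a synthetic scene generator with ground truth for end-to-end
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    png,
    jpeg
Config/testthat/edition: 3
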