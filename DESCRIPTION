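Package: knnfilt
Title: Windowed K-Nearest-Neighbor Guided Filtering of Classification
    Probability Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Spatial-spectral refinement of per-class probability maps from
    pixel-wise classifiers of hyperspectral scenes, guided by a one-band
    image (for example a first principal component). Each pixel's K nearest
    neighbors are found in a feature space combining guidance intensity and
    spatial coordinates, either over the whole image or inside a row-band
    search window, and the per-class posteriors are replaced by the mean
    over those neighbors before label assignment. Includes both Euclidean
    and Manhattan metrics, bounded-insert and full-sort neighbor selection,
    ENVI-style raster input/output, a seeded synthetic scene generator, and
    an evaluation toolkit (difference maps, class-pair misclassification
    breakdown, figure of merit).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
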