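Package: dtwassay
Title: Quantification of Colorimetric Assay Kinetics by Dynamic Time
    Warping and Nearest-Neighbour Matching
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Turns multichannel (RGB) kinetic colour traces from
    nanozyme-based colorimetric assays into concentration estimates.
    Recordings are reduced by non-overlapping block averaging, compared
    with a from-scratch dynamic time warping distance averaged over
    colour channels, and assigned to a concentration grid by
    k-nearest-neighbour matching (k = 1 by default) with leave-one-out
    evaluation. Includes a synthetic-data generator that emulates
    concentration-dependent colour-development kinetics (saturating
    amplitude, first-order development, Beer-Lambert channel response)
    so the full pipeline is testable without recorded video, plus frame
    rendering and region-of-interest extraction for image-based input.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
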