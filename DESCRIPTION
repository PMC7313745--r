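Package: colonycount
Title: Automated Enumeration of Bacterial Colonies on Backlit Agar Plates
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Counts colony-forming units (CFU) in 8-bit grayscale images of
    agar plates recorded with transmissive illumination. Implements a
    five-stage pixel pipeline (rolling-ball background subtraction,
    automatic contrast expansion, disc median filtering, saturating
    brightness lift, and prominence-thresholded regional-minimum
    detection), region-of-interest geometry for whole plates and
    six-segment dilution plates, a seed-controlled synthetic plate
    generator with ground truth, and method-comparison statistics
    (variation coefficients, counting rates, and error-weighted
    regression through the origin) for benchmarking automatic counts
    against manual and on-screen reference enumeration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp (>= 1.0.0),
    png,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
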