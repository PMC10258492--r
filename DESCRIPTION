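Package: myofibr
Title: Automated Myofiber Morphometry for Muscle Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An automated histomorphometry pipeline for skeletal-muscle
    cross-sections stained with Picrosirius Red Fast Green (myofibers green,
    connective tissue red). Segments individual myofibers by stain colour
    separation and marker-controlled watershed (or ingests label masks from an
    external segmenter), converts label masks to per-fiber regions, and
    extracts the two standard morphometric metrics: lesser (minimum Feret)
    diameter and cross-sectional area. Includes per-section summaries and
    fiber-density estimates, 5 um diameter-distribution binning,
    method-agreement metrics (accuracy rate, coefficient of variance,
    productivity), two-group significance testing, a synthetic-histology
    generator with ground truth for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    methods,
    optparse,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
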