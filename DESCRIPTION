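Package: osteodyn
Title: Intravital Osteoclast Motility and Acidification Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multi-channel two-photon time-lapse
    imaging of mature osteoclasts on bone. Implements the mask-overlap cell
    deformation index (A + C)/(A + B) for osteoclast motility, the
    bone-resorbing index (ratio of pH-probe signal inside osteoclast areas
    to noise outside) for osteoclastic acidification, per-pixel nonnegative
    least-squares spectral unmixing to remove autofluorescence, automatic
    segmentation and overlap-based tracking of osteoclast regions, and
    group statistics (mean +/- SD, two-tailed t tests). Includes a synthetic
    time-lapse generator with ground-truth masks that emulates untreated and
    bisphosphonate-treated imaging conditions, so every stage can be
    validated without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
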