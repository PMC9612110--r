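Package: lyomorph
Title: Pore Morphometrics and Sublimation-Front Kinetics from
    Freeze-Drying Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-analysis pipeline for freeze-drying (lyo-)microscopy:
    watershed-based pore segmentation on distance maps, per-pore
    morphometrics (equivalent diameter, aspect ratio, orientation relative
    to the sublimation front), time-lapse tracking of the sublimation
    front with local velocity estimation and primary-drying-time
    derivation, and ROI-level structure-versus-kinetics reporting.
    Includes a calibrated synthetic-micrograph generator with full ground
    truth so every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
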