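Package: fifwbi
Type: Package
Title: Semiautomatic Field-in-Field Planning for Whole-Brain Irradiation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward-planning tools for the field-in-field (FIF) technique in
    whole-brain irradiation with two opposed lateral photon fields. Hotspot
    regions of an original plan are identified in the 3D dose distribution,
    projected into each beam's-eye view, and blocked with automatically fitted
    multileaf-collimator (MLC) sub-beam apertures; beam weights are assigned in
    closed form from the original-plan maximum dose, with a two-step scheme
    that escalates from two to four sub-beams when target coverage degrades.
    Includes a synthetic head-like phantom, a simplified divergent-beam photon
    dose engine, dose-volume-histogram metrics (D95, V105, homogeneity index),
    and NRRD/JSON interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
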