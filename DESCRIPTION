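Package: redoxhcs
Title: Ratiometric roGFP High-Content Screening Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for dual-excitation (405/488 nm) roGFP
    redox imaging in multiwell high-content screens. Provides a fully
    ground-truthed synthetic plate generator emulating mitochondrially
    targeted roGFP photophysics with an H2B nuclear marker and TMRM,
    nuclear-marker-seeded perinuclear ring segmentation alongside
    intensity-threshold segmentation, per-cell ratio quantification,
    Z-prime factor and fold-change hit calling, single-cell time-lapse
    tracking with biphasic change-point detection of redox kinetics,
    and flow-cytometry-style per-event ratio quadrant gating.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
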