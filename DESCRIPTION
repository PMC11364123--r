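Package: complexiqa
Title: Plan Complexity Metrics and Pre-Treatment QA Correlation Analysis
    for Sliding-Window IMRT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how treatment-plan complexity relates to
    pre-treatment verification outcomes in sliding-window intensity-modulated
    radiotherapy (IMRT). Reads DICOM-RT Plan files and a simple JSON plan
    dialect into a validated plan model; derives per-leaf speed and
    acceleration series from control points; computes a 53-metric registry of
    plan complexity metrics (aperture, monitor-unit and MLC-dynamics
    families, including the modulation complexity score, modulation indices
    for leaf speed and acceleration, leaf travel, small-aperture scores and
    edge-area metrics); evaluates global 3D gamma passing rates against
    helical and cross diode-array geometries; generates a synthetic
    site-stratified QA cohort with controllable complexity and orthogonal
    calculation/measurement error channels; and quantifies complexity-QA
    relationships via tie-corrected Spearman correlation with strength
    grading and principal-component regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
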