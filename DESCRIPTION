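Package: cvhseg
Title: Segmented Linear Mixed Models for Longitudinal Cardiovascular Health Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting influential age windows in longitudinal
    cardiovascular health (CVH) trajectories. Implements American Heart
    Association clinical CVH scoring (body mass index, blood pressure, total
    cholesterol, fasting glucose; 0-8 points), segmented (broken-line) linear
    mixed models with maximum-likelihood change-point estimation via iterative
    U/V linearization and delta-method confidence intervals, a brute-force
    profile-likelihood grid oracle, model selection across polynomial and
    segmented mean structures, fixed-knot piecewise interaction models for
    group contrasts, descriptive tables, and a calibrated synthetic
    multi-cohort generator for end-to-end testing and parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
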