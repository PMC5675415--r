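Package: dwbr
Title: Dynamic Weight Bearing Analysis for Rodent Posturography
Version: 0.1.0
Authors@R: person("DWB", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify posturo-locomotor alterations in freely moving
    rats from pressure-plate recordings, as used to follow vestibular
    compensation after unilateral vestibular neurectomy. Provides a synthetic
    rat-on-plate simulator with per-frame ground truth, contact-blob detection
    with wall-contact exclusion, anatomical paw labelling and track linking,
    per-session posture metrics (stance-time fractions, axis-wise weight
    distributions and the PRP/PFP barycenter-like statistic), the 0-15
    vestibular syndrome score, and the longitudinal statistics layer
    (repeated-measures ANOVA, Tukey-Kramer and Bonferroni post-hoc tests,
    F critical-value decisions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    readxl,
    jsonlite,
    withr
Config/testthat/edition: 3
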