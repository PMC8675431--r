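Package: cortlife
Title: Lifespan Trajectories, Harmonization and Normative Centiles for
    Regional Cortical Thickness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling age-related change in regional cortical
    thickness across multi-site cohorts. Provides fractional-polynomial
    age-trajectory regression with exhaustive model enumeration and
    closed-test selection, empirical-Bayes location/scale (ComBat) site
    harmonization, age-group correlation and interindividual-variability
    analyses including random-effects meta-analysis of log standard
    deviations, and LMS (Box-Cox Cole-Green) normative centile curves with
    GAIC-driven smoothness selection. Includes a multi-site synthetic cohort
    generator with known ground truth so the full pipeline can be exercised
    and validated without access to restricted imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    splines,
    sandwich,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    sva,
    jsonlite,
    optparse
Config/testthat/edition: 3
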