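Package: morphoclass
Title: Morphometric Feature Screening and Wrapper Classification for Tremor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for case-case classification of tremor disorders from
    regional MRI morphometry. Reads FreeSurfer-style regional statistics
    tables, builds normalized feature matrices including a cortical
    thickness "roughness" metric (within-region standard deviation of
    thickness), screens features with covariate-adjusted ANCOVA and
    partial eta-squared effect sizes, ranks screened features by the
    information gain ratio of their best binary split, and selects a
    final subset with a greedy forward wrapper driven by cross-validated
    linear support vector machine accuracy. Includes an exhaustive
    subset-search oracle, hard-margin linear-separability reporting, and
    a synthetic cohort generator with planted group effects so the whole
    pipeline can be exercised and calibrated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
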