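Package: collaterals
Title: Whole-Brain Collateral Vessel Scoring and Stroke Outcome Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a whole-brain collateral vessel score for CT-angiography
    vessel grades (weighted aggregation of circle-of-Willis, cerebral artery
    segment, cerebellar and pial collateral assessments), a synthetic stroke
    admission cohort generator with configurable planted effects, a univariate
    association screen (Pearson's r, chi-squared / Cramer's V), multivariate
    linear regression and MANOVA outcome models with subgroup analyses, and a
    reproducible simulate-score-screen-model-report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
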