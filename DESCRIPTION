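Package: interactreg
Title: Interaction Regression for County-Level Crop Yield Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Linear crop-yield prediction from county-year panels of weather,
    soil, and management variables, augmented with kernel-encoded self- and
    two-way environment-by-management interactions. Interactions and features
    are selected by an elastic-net pre-screen followed by a forward/backward
    stepwise search scored on blocked spatio-temporal cross-validation folds,
    so that the selected model is robust across years and county groups.
    Includes yield dissection into additive weather, soil, management, and
    interaction contributions, partial-dependence profiles, in-season
    scenario-ensemble forecasting with historical weather completions, and a
    synthetic county-year panel generator with planted ground truth for
    recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
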