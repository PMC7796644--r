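Package: maintwce
Title: Time-Varying Cumulative-Exposure Cox Models for Maintenance Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-analysis toolkit for maintenance randomized trials in which a
    targeted therapy continues during chemotherapy-free intervals. Implements
    five time-varying cumulative-exposure metrics (cumulative dose, its
    risk-set quantile categories, its risk-set z-score standardization, an
    exponential-decay theoretical blood concentration, and a spline-based
    weighted cumulative exposure) embedded in counting-process Cox
    proportional-hazards models, with AIC model comparison, weight-function
    estimation with pointwise confidence bands, hazard-ratio reconstruction
    for dosing patterns, and a Grambsch-Therneau global proportional-hazards
    test. Includes a synthetic maintenance-trial generator with known
    exposure effects so the full analysis pipeline can be validated by
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
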