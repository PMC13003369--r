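Package: phptfrax
Title: Fracture Risk Validation and Surgical Benefit Stratification in
    Primary Hyperparathyroidism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for validating ten-year fracture-risk scores and
    stratifying the fracture benefit of parathyroidectomy in cohorts of
    patients with primary hyperparathyroidism. Implements seeded synthetic
    cohort generation with confounded treatment assignment and competing
    mortality, a transparent surrogate ten-year fracture-probability
    calculator with competing-risk integration, Aalen-Johansen cumulative
    incidence, decile calibration with least-squares summary lines,
    time-dependent cumulative/dynamic AUROC under censoring with
    influence-function confidence intervals, inverse-probability-of-treatment
    weighted piecewise-exponential Poisson hazard models with a
    score-by-treatment interaction, delta-method hazard-ratio curves, and
    surgical-benefit threshold detection, orchestrated by a reproducible
    pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
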