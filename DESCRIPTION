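Package: lifehorizon
Title: Lifetime Risk, Life Expectancy and Lifetime Medical Cost Estimation
    for Claims-Based Disease Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating lifetime outcomes of a disease cohort
    reconstructed from health-insurance claims: lifetime risk via the
    cumulative incidence rate over ages 18-84, life expectancy and expected
    years of life lost obtained by extrapolating Kaplan-Meier survival
    beyond follow-up with a logit survival-ratio rolling-over algorithm
    against Monte-Carlo matched referents drawn from national life tables,
    and survival-weighted, discounted lifetime healthcare expenditures.
    Includes a synthetic claims-data generator with known ground truth so
    the full pipeline can be exercised and validated without access to
    restricted administrative data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
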