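Package: riskforage
Title: Risk Preference Dynamics Under Changing Environmental Richness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for accept/reject gambling tasks in which the
    richness of the reward environment changes across blocks. Provides the
    task designs (poor, intermediate and rich environments with catch
    trials), risk-return and prospect-theory decision models, a synthetic
    cohort generator, a priori exclusion criteria and pooled acceptance
    descriptives, participant-level bootstrap hypothesis tests, hierarchical
    expectation-maximization model fitting with iBIC model comparison, a
    particle filter with fixed-lag smoothing for the latent group-level
    risk-aversiveness trajectory, trial-history logistic regression with
    forward choice simulation, and risk-sensitive foraging fitness
    simulations over survival thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
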