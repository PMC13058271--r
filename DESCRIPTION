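Package: ltctransfer
Title: Causal Effects of Hospital Transfer on Long-Term-Care Residents
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and estimation toolkit for studying the effect of
    hospital transfer on permanent physical impairment, permanent cognitive
    impairment and mortality among long-term-care residents assessed on a
    92-day (quarterly) grid. Provides a longitudinal cohort simulator with
    home-level transfer-propensity heterogeneity and a latent acute-illness
    confounder; person-period (counting-process) dataset construction with
    the exposure and outcome windowing, permanence and censoring rules of
    quarterly assessment data; incidence rates, rate ratios and standardized
    mean differences; marginal structural models with stabilized
    inverse-probability-of-treatment and censoring weights feeding a weighted
    cause-specific Cox model; and a preference-based instrumental-variable
    analysis via two-stage residual inclusion with cluster bootstrap.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
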