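Package: ibdcea
Title: Cost-Effectiveness of Telemonitoring for IBD Outpatient Care During a
    Pandemic
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision-analytic cost-effectiveness model for outpatient
    management of inflammatory bowel disease (IBD) during the COVID-19
    pandemic, from a public healthcare provider perspective. Implements a
    one-year decision-tree cohort model for standard care with and without
    pandemic-related healthcare avoidance and with a weekly telemonitoring
    programme; incremental analysis with dominance classification, ICER and
    net monetary benefit against a willingness-to-pay threshold; one-way
    deterministic sensitivity analysis with bisection threshold finding and
    tornado ranking; probabilistic sensitivity analysis by seeded Monte
    Carlo with Beta, Gamma, Lognormal and Normal parameter distributions;
    and a patient-level microsimulation used to cross-validate the analytic
    cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
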