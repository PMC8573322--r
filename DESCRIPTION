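Package: riskysearch
Title: Presentation Manner, Information Search, and Risky Choice
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for studying how the manner of
    information presentation (alternative-wise versus dimension-wise) shifts
    risky choice between simple binary gambles. Provides stimulus generation
    under non-dominance constraints, synthetic participants whose choices
    follow expected-value or maximax strategies under a softmax rule,
    maximum-likelihood strategy classification via G-squared model comparison
    against a random-choice baseline, the Bockenholt-Hynan search-measure (SM)
    index computed from area-of-interest fixation transitions, mixed-effect
    regression models for choice and decision time, and a cluster-bootstrap
    mediation analysis of the task -> search direction -> choice chain.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
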