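Package: agestage
Title: Age-Stage, Two-Sex Life Table Analysis for Insect Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds age-stage, two-sex life tables from per-individual
    life-history records of insect cohorts reared under constant conditions:
    age-stage survival matrices (s_xj), age-specific survival (l_x) and
    fecundity (m_x) schedules, stage-duration and reproduction summaries,
    and population growth parameters (net and gross reproductive rates,
    intrinsic and finite rates of increase, mean generation time) with
    bootstrap standard errors and percentile confidence intervals. Includes
    a stochastic cohort simulator with exact expected schedules for
    estimator-recovery studies, development-rate-versus-temperature
    regression, and one-way ANOVA with Fisher LSD compact letter displays
    for comparing treatments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
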