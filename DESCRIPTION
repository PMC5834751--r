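Package: goalstep
Title: Adaptive Step-Down Drinking-Limit Goals, EMA Scheduling, and Cohort Simulation for Text-Message Alcohol Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a just-in-time adaptive intervention (JITAI) engine for
    weekend drinking-limit goal support delivered by text message: an adaptive
    step-down goal policy based on the running average of the prior two weekend
    maxima, a deterministic ecological momentary assessment (EMA) scheduling and
    tailoring state machine with run-in eligibility screening and voluntary
    4-week block re-enrollment, baseline instrument scoring (AUDIT-C, B-YAACQ,
    Daily Drinking Questionnaire, Alcohol Ladder stage coding, NM-ASSIST
    dichotomization), a seeded generative cohort simulator producing engine-format
    event logs, and the analysis battery for such trials: EMA compliance tables,
    goal commitment and success metrics, repeated-measures Poisson trend models
    with participant random intercepts, chi-square association tests, Wilcoxon
    signed-rank tests with exact small-sample p-values, and two-sample proportion
    tests. All user-facing functions take data frames and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    glmmTMB,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
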