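Package: somnus
Title: Autonomous Insomnia Screening and Two-Step Behavioral Sleep Intervention Engine
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A desk-scale engine for a smartphone-style digital sleep
    intervention: Insomnia Severity Index (ISI) screening with severity
    bands and eligibility/referral rules, an electronic sleep diary with
    midnight-safe derivation of the nocturnal sleep indicators (SOL, NWAK,
    TWAK, WASO, TIB, TST, sleep efficiency), an explicit protocol state
    machine for the screening / diary-week / personalized-recommendation
    flow, a declarative rule engine for sleep-hygiene advice, acceptance
    and trust questionnaire scoring, the study's summary statistics
    (Pearson chi-square, pooled and paired t, Pearson correlation), and a
    calibrated synthetic-cohort simulator reproducing the adherence funnel
    and pre/post outcome trajectories so the whole pipeline runs with no
    real user data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
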