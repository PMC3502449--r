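Package: emadiary
Title: Branching Momentary-Assessment Engine for Ambulatory Symptom Diaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An ecological momentary assessment (EMA) engine for ambulatory
    self-report of psychotic and mood symptoms. Provides a validated branching
    item bank (14 symptom scales split over two alternating sets, with a
    personalisable delusion menu), a pseudo-random signal-contingent prompt
    scheduler with snooze and expiry semantics, an adaptive session
    administrator, scale scoring with composites and compliance rules,
    psychometric analyses (within-person mean squared successive difference
    and standard deviation, Cronbach's alpha, Spearman validity tables), and a
    synthetic longitudinal respondent simulator with latent AR(1) symptom
    trajectories, severity-dependent missingness and paired interview ratings,
    so the full pipeline can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
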