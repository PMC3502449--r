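---
title: "Methods: a branching momentary-assessment engine for psychotic symptoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a branching momentary-assessment engine for psychotic symptoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emadiary)
```

## The assessment model

`emadiary` implements a signal-contingent ecological momentary assessment
(EMA) instrument for ambulatory self-report of psychotic and mood symptoms.
Fourteen symptom scales — twelve designed to parallel PANSS interview items
and two to parallel Calgary Depression Scale (CDS) items — are split into two
sets of seven that alternate across prompts, keeping individual sessions
short. Within a scale, stem items are always presented and branch items are
shown only when an earlier response crosses a display threshold, so the
number of questions adapts to current symptom load: exhaustive enumeration of
branch outcomes in the packaged bank gives 15–30 questions for set one and
11–31 for set two (the set-two range spans 0–2 configured delusions).

Responses are captured on an analogue slider and converted to a 7-point
Likert value through seven equal-width bins, `[(k-1)/7, k/7)` with the top
bin closed. The first grandiosity item asks for a self-appraisal relative to
the average person, so only above-average responses are informative; it is
recoded 1–4→1, 5→2, 6→3, 7→4 before scoring.

Because delusional content is heterogeneous, the delusions scale is
personalised: a researcher selects up to two of six packaged belief
statements, each probed for preoccupation, distress and behavioural impact
(four questions per statement). Two reactivity statements ("keeping the
diary has influenced my thoughts / my mood") close every session; they are a
safety outcome, belong to no symptom scale, and measure magnitude only — the
direction of any reactivity is not captured.

## Prompt scheduling

Six alarms a day are drawn over seven days within a 09:00–21:00 window
(42 scheduled entries). The window is split into six equal 120-minute epochs
and one time is drawn uniformly (whole minutes) within each epoch; a draw
closer than 60 minutes to its predecessor is re-drawn within its epoch up to
100 times and then deterministically repaired to the earliest feasible
minute. With 120-minute epochs the repair is always feasible, and the
empirical coverage tests guard against degenerate clamping at epoch edges. A
single snooze re-alerts after 5 minutes; the 15-minute response window is
anchored at the *initial* alarm and does not move, with the boundary minute
counting as on time. Times are whole minutes on the local clock; no
time-zone or DST modelling is attempted.

## Scoring and compliance

A scale score at one time-point is the mean of its answered items on the 1–7
continuum. Branch items that were never displayed are excluded from the mean
rather than imputed at the floor: the instrument's branching already encodes
"absent" in the stem response, and imputing 1s would double-count it. Two
composites mirror how interview raters integrate information: the delusions
composite averages the configured delusion item responses with the
grandiosity, somatic-concern and suspiciousness scale means (with no
delusions configured it degenerates to the mean of the three scale means),
and the depression composite averages the depression items with the
hopelessness scale mean. Delusion sub-items (preoccupation, distress,
impact) are weighted equally — nothing in the instrument's description
suggests otherwise.

Person-level scores are unweighted means over available time-points.
Compliance requires completing at least 33% of the 42 scheduled entries; the
threshold count is the ceiling of the fraction (13.86 → 14), and partial
sessions count as missed — entry counts are complete-or-not, with no partial
credit.

## Psychometric analyses

Within-person instability uses the mean squared successive difference
(MSSD), `mean(diff(x)^2)`, and the sample SD, both over each person's
available scores with missing time-points dropped before differencing (so
successive differences may span gaps). Internal consistency is Cronbach's
alpha computed on pooled completed entries — rows are entries across
participants and time-points, which maximises rows; rows with an untriggered
branch item are incomplete and are dropped, with the retained count reported
in the result. Validity is Spearman's rank correlation between per-person
diary means and the corresponding follow-up interview item (the follow-up
interview covers the sampled week, which is why it, not the baseline, is the
comparator). Rho uses average ranks for ties; p-values use the t
approximation with n−2 degrees of freedom, adequate at the n≈36 where the
table is meant to be read, with an exact permutation p available below n=10.
Scales endorsed above the floor by fewer than three participants are flagged
and excluded from correlation rather than reported on a meaningless base.
Delusion instability rows are restricted to participants who actually had
delusion questions configured.

## The synthetic cohort generator

No participant data ship with the package; the generator exists so every
pipeline stage can be exercised end to end. Each of three severity groups
(acute, remitted, ultra-high-risk) contributes 12 participants, mirroring a
three-arm feasibility design. For each scale, a person's latent severity
follows a stationary AR(1) process on the 1–7 continuum:
`L[1] ~ N(mu, sigma^2/(1-phi^2))`, `L[t+1] = mu + phi (L[t]-mu) + e[t]`,
with the person mean `mu` drawn from a group-specific normal distribution.
AR(1) is the simplest process that produces the persistence-versus-
instability contrast the instrument is meant to detect; per-scale `phi` is
graded so delusions (0.85) and grandiosity (0.80) are the most stable
constructs and passive social withdrawal (0.15) the least, with innovation
SDs sized so latent MSSD, `2 sigma^2/(1+phi)`, spans roughly 0.7–2.7.
Group means put acute participants above remitted and UHR on positive
scales; guilty ideas of reference sit near the floor so the scale is rarely
informative, as floor-level constructs are in practice.

Analogue responses are rendered by squashing the latent value through
`plogis((L-4)/1.5)` — centred mid-continuum with a slope that maps the
latent range onto all seven bins — plus Gaussian item noise (SD 0.06 on the
fraction scale), clamped to [0, 1]. Interview ratings are a clamped, rounded
monotone transform of the person's latent mean plus linkage noise (PANSS
items on 7 levels, CDS items on 4). Because the rounding and clamping make
the closed-form bivariate-normal attenuation formula inexact, the linkage
noise needed for a target diary–interview rank correlation is calibrated
numerically: a large simulated sample with common random numbers and root
finding (`calibrate_interview_noise()`).

Missingness is a per-entry Bernoulli from a logistic model,
`p = plogis(beta0 + log(OR) (severity - 2.5))`, with an odds ratio of 0.68
per unit of positive-symptom severity so that more symptomatic participants
complete fewer entries, and `beta0 = 1.05` so that a participant of average
severity completes about 74% of entries. Missingness is independent across
alarms given the person; no within-week dropout dynamics are modelled.

What the generator does *not* emulate: reactive or time-of-day response
patterns, correlated item errors within a session, response styles
(acquiescence, extreme responding), or informative missingness beyond the
person-level severity effect. Tests passing on simulated cohorts therefore
demonstrate that the engine computes its statistics correctly and recovers
known generating structure, not that the instrument is valid in patients.

## Numerical and design choices

* **Branch trigger**: branches show when the source response is ≥ 2 (any
  endorsement above "absent"); an unanswered or hidden source evaluates
  false. Enumeration of question counts is exact for arbitrary condition
  structures — items are grouped into dependency components and explored
  recursively over the distinct response classes the thresholds induce — and
  is verified against brute force over the full 7^m response grid.
* **Set alternation**: odd global prompt indices give set one, even set two.
* **Reactivity items** are administered at every session; they belong to no
  scale, so this maximises the safety data at no cost to scoring. They are
  counted in the per-set question totals, which is how the packaged bank's
  enumeration lands exactly on 15–30 and 11–31.
* **Sampling design**: the 42-entry week is taken as 7 days × 6 prompts.
* **Undefined statistics** (empty series, zero variance) propagate as
  `NA`/null and are flagged, never coerced to 0.
* **Problem sizes**: the test suite checks analytic MSSD limits at series
  length 1e5, metric oracles on 500 random instances per statistic, schedule
  constraints over 1000 seeds, and linkage recovery over 200 replicate
  cohorts of n = 36 — sizes at which Monte-Carlo error is comfortably inside
  the asserted tolerances while the suite stays fast.

## Known limitations

The packaged item wordings are synthetic stand-ins written to the
instrument's structure (scale names, branch counts, delusion statements and
reactivity items are as published; stem/branch phrasings are not). Scoring
treats suspiciousness and paranoia as one scale. The engine does not model
interview administration itself — interview scores enter as data — and
group-difference inference (ANOVA, regression of dropout predictors) is out
of scope.
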