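---
title: "Digital phenotyping of depression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital phenotyping of depression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digiphen)
```

## The problem

Depression screening relies on questionnaires such as the PHQ-9, which are
administered at discrete time points and suffer from stigma-driven
under-reporting. Passive smartphone telemetry offers a continuous,
zero-burden alternative: the way a person opens apps, how long their
sessions last, how their nightly inactivity looks, and how much their phone
moves during idle periods all shift with depressive state. `digiphen`
implements a complete day-level pipeline from raw event streams to a daily
**Mental Health Similarity Score (MHSS)** — the probability, expressed as a
percentage, that a day of digital behavior resembles that of users
screening positive for severe depression — together with the cohort
statistics needed to interpret it.

## From raw streams to daily biomarkers

Raw inputs are app open/close intervals and gyroscope samples stamped in
UTC milliseconds, plus one baseline PHQ-9 per user. Timestamps are shifted
to the user's local clock using a fixed per-user minute offset (+540,
Korea Standard Time, by default). Daylight-saving shifts are ignored; for
the region the defaults target they do not occur, and a fixed offset keeps
day boundaries reproducible. Each event is assigned to local
midnight-to-midnight days, with midnight-spanning sessions split at the
boundary so that total usage time is conserved exactly (this is tested to
machine precision). Events longer than 24 h are treated as logging
artifacts and clipped.

A day counts as *complete* iff it is neither the first nor the last
calendar day on which the user was observed: edge days are almost surely
partial, and dropping them is the conservative completeness rule when no
observation-window metadata exist.

Per complete day we compute **37 nonsensor features**: five global ones —
mean session time, total session time, number of opens, sleep, average gap
— plus per-category daily time and open counts for the 12 app categories
(0 = nonofficial/unregulated, 1 = social interaction, 2 = passive
information consumption, 3 = active messaging/communication, 6 = general
utilities, 11 = miscellaneous passive recreation; the remaining indices
are deployment-specific), plus "upper" counts — sessions longer than the
category's daily mean plus `k_sd` standard deviations (default
`k_sd = 1`) — for eight configurable categories. The 5 + 12 + 12 + 8
layout is asserted at build time to total 37. Three gyroscope features
complete the vector: the mean, gap-restricted mean, and sum of the
angular-velocity norm over the day's samples.

Two conventions deserve a note. *Sleep* is the longest single inactivity
gap, where the gaps from midnight to the first open and from the last
close to midnight also compete; this makes the nocturnal window the
longest gap on virtually every realistic day and puts the feature in the
hundreds of minutes. *Average gap* uses only the gaps between consecutive
sessions: this keeps it in single-digit minutes for a typical heavy
smartphone user, which is the scale on which cohort differences were
reported for it. A day with no events reports zero counts and times and a
1440-minute sleep gap.

## Labels, observation expansion, and class imbalance

Each user's baseline PHQ-9 total maps to the standard severity bands
(none < 5, mild 5–9, moderate 10–14, moderately severe 15–19, severe
20–27; 20 is inside severe). Four classification tasks are supported:
`binary` (none vs severe, the deployed score), `three_class`
(none/moderate/severe, tracking progression), `questions` (all-zero vs
all-three on the affective-cognitive subscale, items 2, 6 and 9), and
`gyro_binary` (binary plus the three sensor features, restricted to days
that have them).

Every complete day is one observation carrying its user's label, so a
10-day user contributes 10 labeled observations. Class imbalance is
handled by undersampling: each larger class is randomly subsampled without
replacement to the smallest class's size. (The alternative reading —
oversampling the minority — is available as `mode = "over"`, but
undersampling is the only reading under which class counts become equal
without replacement.) Cross-validation is 15-fold and, by default,
*grouped by user*: all of one user's days stay on one side of each split.
Day-level splits of day-expanded data leak within-user structure into the
test folds and flatter the accuracy; both modes are provided so the effect
can be measured, but the grouped mode is the honest default and is what
every reported number in this package uses. An optional bootstrap wrapper
(`nBoot`, default 15) repeats the cross-validation over resamples of the
observation set and aggregates fold metrics as mean ± SD.

## Classifiers and the MHSS

Three algorithms run on library defaults with a fixed seed — random forest
(500 trees), gradient boosting, and an RBF-kernel SVM — deliberately
untuned, since no hyperparameters were specified for the analyses this
package operationalizes; defaults make the comparison reproducible and
the random-forest-vs-SVM ordering is itself one of the checked
properties. The pipeline contains no feature-standardization stage, and
the SVM is run with its internal rescaling switched off so that it sees
the same raw minutes/counts design matrix as the tree models — the
configuration under which an untuned RBF kernel on wildly mixed feature
scales collapses toward chance, which is exactly the behavior of the
untuned SVM comparator being mirrored. The random forest reports Gini (mean decrease in impurity)
importances, normalized to sum to 1 and ranked.

The MHSS of a day is 100 × the binary model's predicted probability of
the severe class. The majority-of-days rule classifies a user as
depressed when strictly more than half of their scored days exceed MHSS
50, as not depressed when strictly more than half fall below, and
otherwise as a tie — a first-class value rather than a coin flip, since
exact-50 days and even splits are genuinely ambiguous. Weekly verdicts
apply the same rule to consecutive 7-day windows counted from the first
scored day. Group-level validation pools days within each severity band
and reports the percentage above the cutoff; with a working model this
percentage increases monotonically from the none to the severe band.

## Cohort statistics

Feature comparisons use Welch's unequal-variance t-test, one-tailed in
the direction of the observed difference: cohort SDs of these features
differ up to ten-fold, which rules out the pooled-variance form. Effect
sizes are Cohen's d magnitudes with a sample-size-weighted pooled SD (an
equal-weight variant is available since per-cohort observation counts are
not always published). Tests are computed over per-day observations,
matching the observation-expansion design. Per-item PHQ-9 correlations
with the baseline-day MHSS are Pearson and Spearman, computed within a
stated band cohort; zero-variance inputs are flagged as undefined rather
than silently zeroed. No multiple-testing correction is applied, matching
the analyses being reproduced.

## The synthetic study generator

No participant data ship with this package; the generator exists so every
stage is testable end to end. Each cohort profile states corpus-level
daily targets for the none/moderate/severe populations: mean session time
1.1 (SD 0.5) / 1.8 / 2.5 (4.8) minutes, opens 305.7 (137.9) / 273 / 240.8
(169.6), sleep 266.7 / 283 / 300 minutes, gyro gap activity 7.6 / 15 /
23.8, with category mixtures anchored to the published per-category open
counts (messaging ≈ 36% of opens for none vs 31% for severe). The
moderate profile has no published moments and sits midway by choice.

A day is built as: a truncated-normal nocturnal sleep window anchored at
local midnight (location-corrected so the truncated mean hits the
target); a log-normal day-level session-duration scale and a log-normal
open-count draw (so between-day heterogeneity matches the heavy-tailed SD
targets); log-normal session durations laid over the active window with
exponential gaps rescaled to fill it exactly. This conditioned renewal
construction recovers the targeted moments by construction rather than by
tuning. Gyroscope samples are placed at a fixed cadence with separate
activity levels during usage and during gaps, per-axis Gaussian with
scale set so the expected vector norm hits the profile level; the cadence
itself is derived from the total-to-mean activity ratio.

Two honest caveats. First, the printed target set is mutually
inconsistent — 240.8 opens × 2.5 min/session ≈ 602 min of daily usage
against a printed total of 416.7, and the gyro totals imply different
sample counts per cohort — so the generator prioritizes mean session
time, opens and sleep, letting average gap and the totals be implied by
the 1440-minute day identity. Second, capping a day's usage at the active
window clips the heaviest log-normal draws, which would bias the severe
cohort's mean session time low; the duration scale carries a
moment-matching multiplier (1.72 for severe, 1.32 for moderate, fixed
points of the capped generator measured at 4000 days) that restores the
corpus mean to within ~2% of target. Realized day-level SDs remain below
the printed ones for the severe cohort (the printed SDs mix between-user
variance the generator does not model); within-user day-to-day
correlation is likewise absent (an AR(1) extension is a known gap). PHQ-9
item compositions are sampled within the band implied by each profile,
with the affective-cognitive items pinned (0s for none, 3s for severe) so
the questions task is well-populated; a histogram-matching mode
reproduces the reference 558-respondent score distribution exactly.

Consequently, passing tests demonstrate that the pipeline recovers known
structure at realistic effect sizes and collapses to chance when that
structure is removed — not that any particular accuracy would be attained
on real participants, whose data are richer, dirtier and
between-user-correlated in ways the generator does not emulate.

## Problem sizes and numerical choices

The end-to-end checks simulate 100 users per cohort with 10 complete days
each (2000 balanced observations, grouped 15-fold CV, one bootstrap
repeat) — large enough that chance-level accuracy concentrates within a
few points of 50% while a calibrated two-cohort contrast separates
comfortably above 70%. Moment-recovery checks use several hundred to a
few thousand simulated days and 5–15% tolerances reflecting Monte-Carlo
error at those sizes. Ties in session-duration thresholds use strict
inequality (`> mean + k·SD`); upper counts need at least two sessions in
the category, otherwise 0. Degenerate statistical inputs (zero variance
in both cohorts with equal means) return d = 0 and p = 0.5 by convention.
All randomness flows from explicit integer seeds; identical seeds give
byte-identical simulated CSVs.

## Worked example

```{r example, eval = FALSE}
cfg <- defaultPipelineConfig()
cfg$simulate$n_users <- 50L       # per cohort: none and severe
cfg$n_boot <- 1L
res <- runPipeline(cfg, seed = 1)
res$report                         # cross-validated ModelReport
res$high_day_fraction              # per-band % of days with MHSS > 50
head(res$comparisons)              # Welch/Cohen-d feature table
```

## Known limitations

* The category taxonomy beyond the six anchored indices is configurable
  but arbitrary; real deployments must supply their own app-category map.
* The completeness rule is a proxy; with true observation-window metadata
  it should be replaced by actual 24-hour coverage.
* The generator matches first moments (and, loosely, second moments) of
  daily features, not their joint distribution, temporal dependence, or
  user-level heterogeneity.
* Accuracies measured on synthetic cohorts say nothing quantitative about
  real-data performance; only the qualitative properties (separability at
  realistic effect sizes, chance at null, monotone MHSS progression,
  RF ≥ SVM untuned ordering) are asserted.
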