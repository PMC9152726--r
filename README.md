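# digiphen

Digital phenotyping of depression from passive smartphone usage streams.

## What this package does

Depression screening is episodic and stigma-laden; passive smartphone
telemetry is continuous and burden-free. `digiphen` implements a complete
day-level pipeline from raw app open/close event logs and gyroscope
samples to a daily **Mental Health Similarity Score (MHSS)**:

1. **Ingest** — parse event/gyro/PHQ-9/user CSVs, resolve app categories,
   localize UTC-millisecond timestamps to the user's fixed offset, and
   split events at local midnight into daily bins (conserving usage time
   exactly).
2. **Featurize** — 37 nonsensor daily biomarkers (mean/total session time,
   opens, sleep = longest inactivity gap, average inter-session gap,
   per-category times/opens/long-session counts over 12 app categories)
   plus 3 gyroscope activity features per user-day, held as a
   `DigitalPhenotypeExperiment` (a `SummarizedExperiment` of features ×
   user-days).
3. **Cohort** — score PHQ-9 baselines into severity bands (none < 5, mild
   5–9, moderate 10–14, moderately severe 15–19, severe ≥ 20), expand
   users into per-day labeled observations, undersample to exact class
   balance, and build user-grouped 15-fold cross-validation splits.
4. **Classify** — random forest (500 trees), gradient boosting, or
   RBF-SVM on library defaults; per-class precision/recall/F1, accuracy,
   and normalized Gini importances. The MHSS of a day is 100 × the binary
   (none vs severe) model's predicted probability of the severe class;
   majority-of-days verdicts call a user depressed when strictly more than
   half of scored days exceed MHSS 50.
5. **Stats** — one-tailed Welch t-tests with Cohen's d across cohorts,
   per-item PHQ-9 × MHSS Pearson/Spearman correlations, and demographic
   summary tables.

A calibrated synthetic study generator (`simulateCohort()`) emits event,
gyro, PHQ-9 and user files whose corpus-level daily moments match the
reference cohort targets (e.g. mean session time 1.1 vs 2.5 minutes and
305.7 vs 240.8 opens/day for the none vs severe profiles), so the whole
pipeline is testable without any participant data.

## Worked example

```r
library(digiphen)
cfg <- defaultPipelineConfig()          # binary task, RF, 15 folds
cfg$simulate$n_users <- 50L             # 50 users per cohort (none, severe)
cfg$n_boot <- 1L                        # plain 15-fold CV
res <- runPipeline(cfg, seed = 1)
res$report
#> ModelReport: task=binary algorithm=random_forest
#>   accuracy: 92.3% (SD 2.1 over 15 folds)
#>   none               precision  92.2  recall  92.6  F1  92.4
#>   severe             precision  92.2  recall  91.9  F1  92.0
#>   top features: app_time_2, app_opens_2, app_opens_3, mean_session_time, app_time_0
res$high_day_fraction
#>     band n_users n_days pct_high
#> 1   none      50    500        0
#> 2 severe      50    500      100
```

Read: cross-validated (user-grouped folds) accuracy of the none-vs-severe
day classifier on the simulated study, the features driving it, and the
percentage of each band's days with MHSS > 50 — near zero for the none
cohort, near 100 for severe. On synthetic data these numbers demonstrate
signal recovery at calibrated effect sizes, not real-world performance;
with identical cohort profiles the same pipeline lands at chance (~50%).

Single days are just as easy:

```r
ev <- data.frame(start_min = c(600, 610, 1200),
                 end_min   = c(602, 614, 1203), category = 3L)
featurizeDay(ev)[c("n_opens", "mean_session_time", "average_gap", "sleep")]
#>           n_opens mean_session_time       average_gap             sleep
#>                 3                 3               297               600
```

(Three sessions of 2/4/3 minutes; the average inter-session gap is
mean(8, 586) = 297 minutes and the longest gap — midnight to the 10:00
first open — is the 600-minute sleep proxy.)

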