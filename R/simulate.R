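# Synthetic event-stream generator. Each cohort profile states corpus-level
# daily targets (minutes/counts); days are built so those moments are
# recovered by construction: a nocturnal sleep window anchored at local
# midnight, then a renewal-style layout of log-normal session durations
# separated by exponential gaps rescaled to fill the active window exactly.
# The printed target set is jointly over-determined (opens x mean session
# time need not equal total session time), so the generator prioritizes
# mean session time, number of opens and sleep; average gap and totals are
# implied by the 1440-minute day identity.

.E_NORM3 <- 2 * sqrt(2 / pi)  # E|N(0,1)_3| = 1.5958; sets per-axis SD

#' Build a cohort profile for the simulator
#'
#' Defaults (per label) anchor the corpus-level feature targets to the
#' reference cohort's daily moments: e.g. the `none` profile targets a mean
#' session time of 1.1 (SD 0.5) minutes, 305.7 (SD 137.9) opens and 266.7
#' (SD 183.3) minutes of sleep per day, while `severe` targets 2.5 (4.8)
#' minutes, 240.8 (169.6) opens and 300.0 (216.7) minutes, with elevated
#' gyroscope activity during usage gaps (23.8 vs 7.6). The `moderate`
#' profile has no published moments and sits midway. Category mixtures are
#' anchored to the published per-category open counts (e.g. messaging apps,
#' category 3, account for 110.49/305.7 opens for `none` vs 74.45/240.8 for
#' `severe`).
#'
#' @param label `"none"`, `"moderate"` or `"severe"`.
#' @param ... named overrides of any profile field (e.g. `nOpens`,
#'   `meanSessionTime`, `categoryWeights`, `daysMean`).
#' @return a `CohortProfile` (classed list) with derived fields filled in:
#'   truncation-corrected sleep location, per-axis gyro scales, and the
#'   number of gyro samples per day implied by the total/mean activity
#'   targets.
#' @export
cohortProfile <- function(label = c("none", "moderate", "severe"), ...) {
  label <- match.arg(label)
  p <- switch(label,
    none = list(
      meanSessionTime = 1.1, sdSessionTime = 0.5,
      nOpens = 305.7, sdOpens = 137.9,
      sleepMean = 266.7, sleepSd = 183.3,
      categoryWeights = c(0.060, 0.120, 0.007, 0.361, 0.0437, 0.0437,
                          0.100, 0.0437, 0.0437, 0.0437, 0.0437, 0.090),
      gyroMeanActivity = 28.5, gyroGapActivity = 7.6,
      gyroTotalActivity = 1181.6),
    moderate = list(
      meanSessionTime = 1.8, sdSessionTime = 2.5,
      nOpens = 273.0, sdOpens = 154.0,
      sleepMean = 283.0, sleepSd = 200.0,
      categoryWeights = c(0.075, 0.135, 0.005, 0.335, 0.0408, 0.0408,
                          0.100, 0.0408, 0.0408, 0.0408, 0.0408, 0.105),
      gyroMeanActivity = 43.0, gyroGapActivity = 15.0,
      gyroTotalActivity = 1173.0),
    severe = list(
      meanSessionTime = 2.5, sdSessionTime = 4.8,
      nOpens = 240.8, sdOpens = 169.6,
      sleepMean = 300.0, sleepSd = 216.7,
      categoryWeights = c(0.090, 0.150, 0.002, 0.309, 0.0382, 0.0382,
                          0.100, 0.0382, 0.0382, 0.0382, 0.0382, 0.120),
      gyroMeanActivity = 57.0, gyroGapActivity = 23.8,
      gyroTotalActivity = 1165.0))
  p$label <- label
  p$withinDayCv <- 1.5       # per-event duration spread inside one day
  p$daysMean <- 10.7         # observed days per user
  p$daysSd <- 23.7
  p$sleepLo <- 120; p$sleepHi <- 1200
  # moment-matching multipliers: day-capping clips the heaviest session
  # draws, so the input duration scale is inflated so the realized corpus
  # mean hits the target (fixed-point of the capped generator)
  p$durCal <- switch(label, none = 1, moderate = 1.32, severe = 1.72)
  p$opensCal <- 1
  over <- list(...)
  p[names(over)] <- over
  p$categoryWeights <- p$categoryWeights / sum(p$categoryWeights)
  if (length(p$categoryWeights) != 12L)
    stop("categoryWeights must have length 12")
  stopifnot(p$meanSessionTime > 0, p$nOpens > 0, p$sleepMean > 0)
  # location shift so the truncated-normal sleep mean hits the target
  p$sleepMu <- .truncnormLocation(p$sleepMean, p$sleepSd, p$sleepLo, p$sleepHi)
  # split overall gyro activity into usage-time and gap-time levels so both
  # the overall mean and the gap mean are recovered
  usageFrac <- min(0.95, p$nOpens * p$meanSessionTime / (1440 - p$sleepMean))
  p$gyroUsageActivity <-
    max(p$gyroGapActivity,
        (p$gyroMeanActivity - (1 - usageFrac) * p$gyroGapActivity) / usageFrac)
  p$nGyroSamples <- max(0L, as.integer(round(
    if (p$gyroMeanActivity > 0)
      p$gyroTotalActivity / p$gyroMeanActivity else 0)))
  class(p) <- "CohortProfile"
  p
}

# mean of Normal(mu, sd) truncated to [a, b]
.truncnormMean <- function(mu, sd, a, b) {
  al <- (a - mu) / sd; be <- (b - mu) / sd
  mu + sd * (stats::dnorm(al) - stats::dnorm(be)) /
    (stats::pnorm(be) - stats::pnorm(al))
}

.truncnormLocation <- function(target, sd, a, b) {
  stats::uniroot(function(mu) .truncnormMean(mu, sd, a, b) - target,
                 interval = c(target - 3 * sd, target + 3 * sd))$root
}

.rtruncnorm <- function(n, mu, sd, a, b) {
  u <- stats::runif(n, stats::pnorm(a, mu, sd), stats::pnorm(b, mu, sd))
  stats::qnorm(u, mu, sd)
}

# log-normal draws with given mean and coefficient of variation
.rlnormMeanCv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, log(mean) - s2 / 2, sqrt(s2))
}

#' @export
print.CohortProfile <- function(x, ...) {
  cat(sprintf(paste0("CohortProfile '%s': %.1f opens/day, mean session ",
                     "%.2f min, sleep %.0f min, gap activity %.1f\n"),
              x$label, x$nOpens, x$meanSessionTime, x$sleepMean,
              x$gyroGapActivity))
  invisible(x)
}

#' Default cohort profiles
#'
#' @return named list of the `none`, `moderate` and `severe`
#'   [cohortProfile()]s.
#' @export
defaultProfiles <- function() {
  list(none = cohortProfile("none"),
       moderate = cohortProfile("moderate"),
       severe = cohortProfile("severe"))
}

#' Simulate one user-day of events and gyroscope samples
#'
#' Draws the day's sleep-window length (truncated normal), the number of
#' opens and a day-level session-duration scale (log-normal, so day-to-day
#' heterogeneity matches the heavy-tailed corpus SD targets), lays sessions
#' with log-normal durations and exponential gaps over the active window,
#' assigns app categories from the profile mixture, and places gyroscope
#' samples at a fixed cadence with the profile's usage-time and gap-time
#' activity levels. Uses the current RNG stream.
#'
#' @param profile a [cohortProfile()].
#' @param gyro also generate gyroscope samples.
#' @return list with `events` (`start_min`, `end_min`, `category`,
#'   `app_id`) and `gyro` (`t_min`, `wx`, `wy`, `wz`), both in minutes from
#'   local midnight.
#' @export
simulateUserDay <- function(profile, gyro = TRUE) {
  L <- .rtruncnorm(1, profile$sleepMu, profile$sleepSd,
                   profile$sleepLo, profile$sleepHi)
  A <- 1440 - L
  n <- max(1L, as.integer(round(
    .rlnormMeanCv(1, profile$nOpens * profile$opensCal,
                  profile$sdOpens / profile$nOpens))))
  dayMean <- .rlnormMeanCv(1, profile$meanSessionTime * profile$durCal,
                           profile$sdSessionTime / profile$meanSessionTime)
  dur <- .rlnormMeanCv(n, dayMean, profile$withinDayCv)
  if (sum(dur) > 0.95 * A) dur <- dur * 0.95 * A / sum(dur)
  g <- stats::rexp(n + 1L)
  g <- g / sum(g) * (A - sum(dur))
  start <- L + cumsum(g)[seq_len(n)] + c(0, cumsum(dur))[seq_len(n)]
  cat <- sample(0:11, n, replace = TRUE, prob = profile$categoryWeights)
  ev <- data.frame(start_min = start, end_min = start + dur,
                   category = as.integer(cat),
                   app_id = sprintf("c%02d.app%d", cat,
                                    sample(3L, n, replace = TRUE)))
  gy <- NULL
  if (gyro && profile$nGyroSamples > 0L) {
    cad <- A / profile$nGyroSamples
    t <- seq(L + stats::runif(1, 0, cad), 1440, by = cad)
    inEvent <- rep(FALSE, length(t))
    for (i in seq_len(n))
      inEvent <- inEvent | (t >= ev$start_min[i] & t < ev$end_min[i])
    level <- ifelse(inEvent, profile$gyroUsageActivity,
                    profile$gyroGapActivity)
    sig <- level / .E_NORM3
    gy <- data.frame(t_min = t,
                     wx = stats::rnorm(length(t), 0, sig),
                     wy = stats::rnorm(length(t), 0, sig),
                     wz = stats::rnorm(length(t), 0, sig))
  }
  list(events = ev, gyro = gy)
}

#' Simulate one PHQ-9 response consistent with a profile's band
#'
#' The total is drawn within the profile's severity band with weights taken
#' from the reference score histogram ([referencePhq9Histogram()]), then
#' spread over items. For `severe` profiles, items 2, 6 and 9 are pinned at
#' 3 (the affective-cognitive subscale maxes out, supporting the questions
#' model); for `none` they are pinned at 0.
#'
#' @param profile a [cohortProfile()].
#' @param userId carried into the record.
#' @return a scored one-row record, as from [scorePhq9()].
#' @export
simulatePhq9 <- function(profile, userId = NA_character_) {
  hist <- referencePhq9Histogram()
  rng <- switch(profile$label, none = 0:4, moderate = 10:14, severe = 20:27)
  w <- hist$n[hist$total %in% rng]
  total <- sample(rng, 1L, prob = w + 0.5)
  items <- integer(9)
  free <- switch(profile$label,
    none = {items[c(2, 6, 9)] <- 0L; setdiff(1:9, c(2, 6, 9))},
    severe = {items[c(2, 6, 9)] <- 3L; setdiff(1:9, c(2, 6, 9))},
    moderate = 1:9)
  items[free] <- .distributePoints(total - sum(items), length(free))
  scorePhq9(items, userId)
}

# random composition of `total` points over `k` slots capped at 3 each
.distributePoints <- function(total, k, cap = 3L) {
  stopifnot(total >= 0, total <= k * cap)
  x <- integer(k)
  for (p in seq_len(total)) {
    open <- which(x < cap)
    i <- if (length(open) == 1L) open else sample(open, 1L)
    x[i] <- x[i] + 1L
  }
  x
}

#' Simulate a labeled multi-cohort study
#'
#' Generates users, their PHQ-9 baselines, and day-by-day event and
#' gyroscope streams in the raw ingest formats (UTC-millisecond
#' timestamps). Each user's first and last simulated calendar days act as
#' partial edge days: `nDaysPerUser` counts the interior days that survive
#' the completeness rule, and two extra edge days are generated around
#' them. Demographics are drawn from the reference cohort's marginals.
#' Identical `seed` gives identical output.
#'
#' @param profiles named list of [cohortProfile()]s (e.g.
#'   [defaultProfiles()] or a subset).
#' @param nUsers users per profile; recycled over profiles.
#' @param nDaysPerUser complete days per user; `NULL` draws each user's
#'   span from the profile's log-normal days distribution (mean 10.7, SD
#'   23.7, truncated at 1).
#' @param seed integer seed; all randomness flows from it.
#' @param startDate local calendar date of the first (edge) day.
#' @param tzOffsetMinutes fixed local-time offset, +540 (Korea) by default.
#' @param gyro generate the gyroscope stream.
#' @param idPrefix prefix for generated user ids; give distinct prefixes
#'   when merging several simulated cohorts so ids cannot collide.
#' @param outDir when given, also writes `events.csv`, `gyro.csv`,
#'   `phq9.csv`, `users.csv` and `categories.yaml` there.
#' @return list with data.frames `events`, `gyro`, `phq9`, `users`, the
#'   named integer vector `categories`, and `cohorts` (user id -> profile
#'   label).
#' @export
simulateCohort <- function(profiles, nUsers = 50L, nDaysPerUser = 10L,
                           seed = 1L, startDate = as.Date("2021-11-01"),
                           tzOffsetMinutes = 540L, gyro = TRUE,
                           idPrefix = "u", outDir = NULL) {
  if (is.null(names(profiles)))
    names(profiles) <- vapply(profiles, `[[`, "", "label")
  nUsers <- rep_len(as.integer(nUsers), length(profiles))
  demo <- referenceDemographics()
  .withSeed(seed, {
    users <- list(); phq <- list(); evs <- list(); gys <- list()
    uid <- 0L
    for (pi in seq_along(profiles)) {
      prof <- profiles[[pi]]
      for (u in seq_len(nUsers[pi])) {
        uid <- uid + 1L
        id <- sprintf("%s%04d", idPrefix, uid)
        nd <- if (is.null(nDaysPerUser))
          max(1L, as.integer(round(.rlnormMeanCv(1, prof$daysMean,
                                                 prof$daysSd / prof$daysMean))))
          else as.integer(nDaysPerUser)
        dayIdx <- as.integer(startDate) + seq_len(nd + 2L) - 1L
        dayList <- lapply(dayIdx, function(d) {
          sim <- simulateUserDay(prof, gyro = gyro)
          localMs <- function(m) round(d * 86400000 + m * 60000)
          ev <- data.frame(user_id = id, app_id = sim$events$app_id,
                           start_utc_ms = localMs(sim$events$start_min) -
                             tzOffsetMinutes * 60000,
                           end_utc_ms = localMs(sim$events$end_min) -
                             tzOffsetMinutes * 60000)
          gy <- if (!is.null(sim$gyro))
            data.frame(user_id = id,
                       t_utc_ms = localMs(sim$gyro$t_min) -
                         tzOffsetMinutes * 60000,
                       wx = sim$gyro$wx, wy = sim$gyro$wy, wz = sim$gyro$wz)
          list(ev = ev, gy = gy)
        })
        evs[[uid]] <- do.call(rbind, lapply(dayList, `[[`, "ev"))
        gys[[uid]] <- do.call(rbind, lapply(dayList, `[[`, "gy"))
        phq[[uid]] <- simulatePhq9(prof, id)
        nodx <- c(none = 1, mild = 113 / 124, moderate = 145 / 162,
                  moderately_severe = 119 / 134, severe = 59 / 75)
        users[[uid]] <- data.frame(
          user_id = id, cohort = prof$label,
          age_bracket = sample(names(demo$age), 1L, prob = demo$age),
          gender = {
            gb <- demo$gender_by_band
            row <- gb[gb$band == as.character(phq[[uid]]$band), ]
            sample(c("male", "female", "other"), 1L,
                   prob = as.numeric(row[, c("male", "female", "other")]))
          },
          language = sample(names(demo$language), 1L, prob = demo$language),
          prior_diagnosis = if (stats::runif(1) <
                                nodx[[as.character(phq[[uid]]$band)]])
            "none" else "depression",
          tz_offset_minutes = as.integer(tzOffsetMinutes))
      }
    }
    out <- list(events = do.call(rbind, evs),
                gyro = if (gyro) do.call(rbind, gys) else NULL,
                phq9 = do.call(rbind, phq),
                users = do.call(rbind, users),
                categories = simCategoryMap(),
                cohorts = stats::setNames(
                  do.call(rbind, users)$cohort,
                  do.call(rbind, users)$user_id))
  })
  rownames(out$events) <- rownames(out$users) <- rownames(out$phq9) <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$events, file.path(outDir, "events.csv"),
                     row.names = FALSE)
    if (!is.null(out$gyro))
      utils::write.csv(out$gyro, file.path(outDir, "gyro.csv"),
                       row.names = FALSE)
    utils::write.csv(out$phq9, file.path(outDir, "phq9.csv"),
                     row.names = FALSE)
    utils::write.csv(out$users, file.path(outDir, "users.csv"),
                     row.names = FALSE)
    yaml::write_yaml(as.list(out$categories),
                     file.path(outDir, "categories.yaml"))
  }
  out
}

#' App-id to category map used by the simulator
#'
#' @return named integer vector mapping the simulator's synthetic app ids
#'   (`c00.app1` ... `c11.app3`) to categories 0-11.
#' @export
simCategoryMap <- function() {
  ids <- as.vector(outer(sprintf("c%02d", 0:11), paste0(".app", 1:3),
                         paste0))
  stats::setNames(rep(0:11, times = 3), ids)
}

#' PHQ-9 cohort matching the reference histogram exactly
#'
#' Generates one scored record per reference respondent so the score
#' histogram (and hence the band counts 63/124/162/134/75) is reproduced
#' exactly; item compositions are random given each total.
#'
#' @param seed integer seed for the item compositions.
#' @return data.frame of 558 scored records.
#' @export
simulateReferencePhq9 <- function(seed = 1L) {
  hist <- referencePhq9Histogram()
  .withSeed(seed, {
    rows <- list()
    uid <- 0L
    for (i in seq_len(nrow(hist))) {
      for (r in seq_len(hist$n[i])) {
        uid <- uid + 1L
        items <- .distributePoints(hist$total[i], 9L)
        rows[[uid]] <- scorePhq9(items, sprintf("r%03d", uid))
      }
    }
    out <- do.call(rbind, rows)
  })
  out
}
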