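# Daily digital biomarkers. All time features are minutes; a day is the
# local midnight-to-midnight window [0, 1440).

#' Layout of the daily feature vector
#'
#' The nonsensor layout is 5 global features (`mean_session_time`,
#' `total_session`, `n_opens`, `sleep`, `average_gap`) plus per-category
#' daily time and open counts for all 12 app categories, plus long-session
#' ("upper") counts for a configurable subset of categories - 8 by default,
#' giving 5 + 12 + 12 + 8 = 37 nonsensor features. Three gyroscope features
#' (`gyro_mean_activity`, `gyro_avg_gap_activity`, `gyro_total_activity`)
#' complete the vector.
#'
#' @param upperCategories integer categories that get an upper-count
#'   feature. The default covers the six named categories of the taxonomy
#'   (0, 1, 2, 3, 6, 11) plus 4 and 5.
#' @param gyro include the three gyroscope feature names.
#' @return character vector of feature names in canonical order.
#' @examples
#' length(featureLayout(gyro = FALSE))  # 37
#' @export
featureLayout <- function(upperCategories = c(0L, 1L, 2L, 3L, 4L, 5L, 6L, 11L),
                          gyro = TRUE) {
  upperCategories <- sort(unique(as.integer(upperCategories)))
  if (any(upperCategories < 0L | upperCategories > 11L))
    stop("upper categories must lie in 0..11")
  nm <- c("mean_session_time", "total_session", "n_opens", "sleep",
          "average_gap",
          paste0("app_time_", 0:11),
          paste0("app_opens_", 0:11),
          paste0("app_upper_", upperCategories))
  if (gyro)
    nm <- c(nm, "gyro_mean_activity", "gyro_avg_gap_activity",
            "gyro_total_activity")
  nm
}

#' Count unusually long sessions in one app category
#'
#' Counts the day's sessions in `category` whose duration exceeds the mean
#' plus `kSd` sample standard deviations of that category's durations on
#' that day. With fewer than two sessions in the category there is no
#' spread to measure and the count is 0; with `kSd = 0` it counts sessions
#' strictly above the category mean.
#'
#' @param dayEvents one day's events (needs `start_min`, `end_min`,
#'   `category`).
#' @param category integer app category 0-11.
#' @param kSd nonnegative SD multiplier (default 1).
#' @return integer count.
#' @export
upperSessionCount <- function(dayEvents, category, kSd = 1) {
  if (length(category) != 1L || is.na(category) ||
      category < 0 || category > 11)
    stop("unknown app category: ", category)
  if (kSd < 0) stop("kSd must be nonnegative")
  dur <- with(dayEvents[dayEvents$category == category, , drop = FALSE],
              end_min - start_min)
  .upperCount(dur, kSd)
}

.upperCount <- function(dur, kSd) {
  if (length(dur) < 2L) return(0L)
  sum(dur > mean(dur) + kSd * stats::sd(dur))
}

#' Gyroscope activity features for one day
#'
#' The activity of a sample is the Euclidean norm of its angular-velocity
#' vector. `mean_activity` averages the norm over all of the day's samples,
#' `total_activity` sums it, and `avg_gap_activity` averages it over the
#' samples that fall outside every app-usage interval (i.e. during usage
#' gaps, where phone movement without screen interaction is informative).
#' An empty sample stream yields three `NA`s, which excludes the day from
#' the sensor-model cohort; a day with samples but none in gaps reports
#' `avg_gap_activity = 0`.
#'
#' @param dayGyro one day's samples (`t_min`, `wx`, `wy`, `wz`), possibly
#'   empty or `NULL`.
#' @param dayEvents one day's usage events (`start_min`, `end_min`).
#' @return named numeric of length 3.
#' @export
gyroFeatures <- function(dayGyro, dayEvents) {
  out <- c(gyro_mean_activity = NA_real_, gyro_avg_gap_activity = NA_real_,
           gyro_total_activity = NA_real_)
  if (is.null(dayGyro) || !nrow(dayGyro)) return(out)
  norm <- sqrt(dayGyro$wx^2 + dayGyro$wy^2 + dayGyro$wz^2)
  inEvent <- rep(FALSE, length(norm))
  for (i in seq_len(nrow(dayEvents)))
    inEvent <- inEvent | (dayGyro$t_min >= dayEvents$start_min[i] &
                          dayGyro$t_min < dayEvents$end_min[i])
  out["gyro_mean_activity"] <- mean(norm)
  out["gyro_avg_gap_activity"] <- if (any(!inEvent)) mean(norm[!inEvent]) else 0
  out["gyro_total_activity"] <- sum(norm)
  out
}

#' Compute the daily feature vector for one user-day
#'
#' Global features: `mean_session_time` and `total_session` are the mean and
#' sum of session durations; `n_opens` counts sessions; `average_gap` is the
#' mean inactivity gap between consecutive sessions; `sleep` is the longest
#' single gap, where the day-edge gaps (midnight to first open, last close
#' to midnight) also count - the longest daily gap is the sleep proxy. A day
#' with no events reports zero counts and times, `sleep = 1440`, and
#' `mean_session_time = average_gap = 0` by convention.
#'
#' @param dayEvents the day's events, clipped to `[0, 1440]` minutes
#'   (`start_min`, `end_min`, `category`); may have zero rows.
#' @param dayGyro the day's gyroscope samples or `NULL`.
#' @param kSd SD multiplier for the upper counts, see [upperSessionCount()].
#' @param upperCategories categories receiving upper counts, see
#'   [featureLayout()].
#' @return named numeric vector following [featureLayout()].
#' @examples
#' ev <- data.frame(start_min = c(600, 610, 1200),
#'                  end_min = c(602, 614, 1203), category = 3L)
#' featurizeDay(ev)[c("n_opens", "average_gap", "sleep")]
#' @export
featurizeDay <- function(dayEvents, dayGyro = NULL, kSd = 1,
                         upperCategories = c(0L, 1L, 2L, 3L, 4L, 5L, 6L,
                                             11L)) {
  layout <- featureLayout(upperCategories, gyro = TRUE)
  v <- stats::setNames(numeric(length(layout)), layout)
  ev <- dayEvents[order(dayEvents$start_min), , drop = FALSE]
  n <- nrow(ev)
  if (n) {
    dur <- ev$end_min - ev$start_min
    gaps <- if (n > 1L) pmax(ev$start_min[-1L] - ev$end_min[-n], 0) else
      numeric(0)
    v["mean_session_time"] <- mean(dur)
    v["total_session"] <- sum(dur)
    v["n_opens"] <- n
    v["average_gap"] <- if (length(gaps)) mean(gaps) else 0
    v["sleep"] <- max(c(ev$start_min[1L], gaps, 1440 - ev$end_min[n]))
    for (c in 0:11) {
      sel <- ev$category == c
      v[paste0("app_time_", c)] <- sum(dur[sel])
      v[paste0("app_opens_", c)] <- sum(sel)
    }
    for (c in sort(unique(as.integer(upperCategories))))
      v[paste0("app_upper_", c)] <- .upperCount(dur[ev$category == c], kSd)
  } else {
    v["sleep"] <- 1440
  }
  v[c("gyro_mean_activity", "gyro_avg_gap_activity", "gyro_total_activity")] <-
    gyroFeatures(dayGyro, ev)
  v
}

#' Featurize all user-days into a DigitalPhenotypeExperiment
#'
#' Applies [featurizeDay()] to every user-day in a binned event stream and
#' assembles the results as a [DigitalPhenotypeExperiment] (features in
#' rows, user-days in columns), with the completeness flag from
#' [dayTable()] in `colData`.
#'
#' @param binnedEvents output of [binEventsByDay()].
#' @param binnedGyro output of [binGyroByDay()], or `NULL` when no sensor
#'   stream was collected.
#' @inheritParams featurizeDay
#' @return a [DigitalPhenotypeExperiment].
#' @export
featurize <- function(binnedEvents, binnedGyro = NULL, kSd = 1,
                      upperCategories = c(0L, 1L, 2L, 3L, 4L, 5L, 6L, 11L)) {
  days <- dayTable(binnedEvents)
  evKey <- paste(binnedEvents$user_id, binnedEvents$local_date)
  evSplit <- split(seq_len(nrow(binnedEvents)), evKey)
  gySplit <- if (!is.null(binnedGyro))
    split(seq_len(nrow(binnedGyro)),
          paste(binnedGyro$user_id, binnedGyro$local_date)) else list()
  keys <- paste(days$user_id, days$local_date)
  mat <- vapply(keys, function(k) {
    ev <- binnedEvents[evSplit[[k]], , drop = FALSE]
    gy <- if (length(gySplit) && !is.null(gySplit[[k]]))
      binnedGyro[gySplit[[k]], , drop = FALSE] else NULL
    featurizeDay(ev, gy, kSd = kSd, upperCategories = upperCategories)
  }, numeric(length(featureLayout(upperCategories, gyro = TRUE))))
  colnames(mat) <- sprintf("%s.%s", days$user_id, days$local_date)
  cd <- S4Vectors::DataFrame(user_id = days$user_id,
                             local_date = days$local_date,
                             complete = days$complete,
                             row.names = colnames(mat))
  new("DigitalPhenotypeExperiment",
      SummarizedExperiment(assays = list(features = mat), colData = cd),
      kSd = kSd)
}
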