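# Reading raw streams and slicing them into local-midnight daily bins.
# All raw timestamps are UTC milliseconds since the epoch; local time is a
# fixed per-user minute offset (no DST), +540 (Korea) by default.

.MS_MIN <- 60000
.MS_DAY <- 86400000
.MIN_DAY <- 1440

#' Read an app-category map
#'
#' A category map assigns every known app identifier to one of 12 integer
#' app categories 0-11 (0 = nonofficial/unregulated, 1 = social interaction,
#' 2 = passive information consumption, 3 = active messaging and
#' communication, 6 = general utilities, 11 = miscellaneous/additional
#' passive recreational; the remaining indices are deployment-specific).
#' Accepts a YAML mapping (`app_id: category`) or a two-column CSV with
#' columns `app_id,category`.
#'
#' @param path path to a `.yaml`/`.yml` or `.csv` file.
#' @return named integer vector, app id -> category.
#' @export
readCategoryMap <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    m <- yaml::read_yaml(path)
    out <- vapply(m, function(x) as.integer(x), integer(1))
  } else {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("app_id", "category") %in% names(d)))
      stop("category CSV needs columns app_id, category")
    out <- as.integer(d$category)
    names(out) <- d$app_id
  }
  if (any(out < 0L | out > 11L)) stop("categories must lie in 0..11")
  out
}

#' Read app-usage events
#'
#' Reads open/close intervals (`user_id,app_id,start_utc_ms,end_utc_ms`) and
#' resolves each app to its category. Apps absent from the map fall into
#' category 0 (nonofficial or unregulated). Rows with `end < start` are
#' dropped with a warning; intervals longer than 24 h are clipped to 24 h
#' (logging artifacts).
#'
#' @param path CSV path, or a data.frame already holding the four columns.
#' @param categoryMap named integer vector from [readCategoryMap()].
#' @return data.frame of events with a resolved `category` column; the
#'   number of dropped rows is in `attr(, "dropped")`.
#' @export
readEvents <- function(path, categoryMap) {
  d <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("user_id", "app_id", "start_utc_ms", "end_utc_ms")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("events input lacks column(s): ", paste(miss, collapse = ", "))
  d$start_utc_ms <- as.numeric(d$start_utc_ms)
  d$end_utc_ms <- as.numeric(d$end_utc_ms)
  bad <- !is.finite(d$start_utc_ms) | !is.finite(d$end_utc_ms) |
    d$end_utc_ms < d$start_utc_ms
  if (any(bad)) {
    warning(sum(bad), " malformed event row(s) dropped")
    d <- d[!bad, , drop = FALSE]
  }
  over <- d$end_utc_ms - d$start_utc_ms > .MS_DAY
  if (any(over)) {
    message(sum(over), " event(s) longer than 24 h clipped")
    d$end_utc_ms[over] <- d$start_utc_ms[over] + .MS_DAY
  }
  cat <- unname(categoryMap[d$app_id])
  unmapped <- is.na(cat)
  if (any(unmapped))
    message(sum(unmapped), " event(s) with unmapped app id assigned category 0")
  cat[unmapped] <- 0L
  d$category <- as.integer(cat)
  d <- d[order(d$user_id, d$start_utc_ms), , drop = FALSE]
  rownames(d) <- NULL
  attr(d, "dropped") <- sum(bad)
  d
}

#' Read gyroscope samples
#'
#' @param path CSV with columns `user_id,t_utc_ms,wx,wy,wz` (angular
#'   velocity components, rad/s), or an equivalent data.frame.
#' @return data.frame sorted by user and time.
#' @export
readGyro <- function(path) {
  d <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("user_id", "t_utc_ms", "wx", "wy", "wz")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("gyro input lacks column(s): ", paste(miss, collapse = ", "))
  keep <- is.finite(d$t_utc_ms) & is.finite(d$wx) & is.finite(d$wy) &
    is.finite(d$wz)
  if (!all(keep)) {
    warning(sum(!keep), " malformed gyro row(s) dropped")
    d <- d[keep, , drop = FALSE]
  }
  d <- d[order(d$user_id, d$t_utc_ms), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Read user metadata
#'
#' @param path CSV with columns `user_id,age_bracket,gender,language,
#'   prior_diagnosis,tz_offset_minutes`, or an equivalent data.frame.
#'   Missing `tz_offset_minutes` defaults to +540 (Korea Standard Time).
#' @return data.frame, one row per user.
#' @export
readUsers <- function(path) {
  d <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"user_id" %in% names(d)) stop("users input lacks column user_id")
  if (!"tz_offset_minutes" %in% names(d)) d$tz_offset_minutes <- 540L
  d$tz_offset_minutes[is.na(d$tz_offset_minutes)] <- 540L
  if (anyDuplicated(d$user_id)) stop("duplicate user_id in users table")
  d
}

#' Bin events into local calendar days
#'
#' Converts UTC-millisecond intervals to the user's local clock (fixed
#' per-user minute offset) and assigns every event to local midnight-to-
#' midnight days. Events spanning midnight are split at each boundary into
#' clipped segments, so no output event crosses a day edge and total usage
#' time is conserved exactly.
#'
#' @param events data.frame from [readEvents()].
#' @param tzOffsetMinutes either a single offset applied to all users, or a
#'   named vector / `users` data.frame giving one offset per user.
#' @return the events with added columns `local_date` (Date), `start_min`
#'   and `end_min` (minutes from local midnight, in `[0, 1440]`).
#' @export
binEventsByDay <- function(events, tzOffsetMinutes = 540) {
  off <- .resolveOffsets(events$user_id, tzOffsetMinutes)
  s <- events$start_utc_ms + off * .MS_MIN
  e <- events$end_utc_ms + off * .MS_MIN
  d <- events
  d$.s <- s
  d$.e <- e
  # iteratively split any segment that extends past its day's end;
  # every event spans < 24 h so at most two passes run
  out <- list()
  repeat {
    dayEnd <- (floor(d$.s / .MS_DAY) + 1) * .MS_DAY
    over <- d$.e > dayEnd
    done <- d[!over, , drop = FALSE]
    out[[length(out) + 1L]] <- done
    if (!any(over)) break
    head <- d[over, , drop = FALSE]
    tail <- head
    head$.e <- dayEnd[over]
    tail$.s <- dayEnd[over]
    out[[length(out)]] <- rbind(done, head)
    d <- tail
  }
  d <- do.call(rbind, out)
  day <- floor(d$.s / .MS_DAY)
  d$local_date <- as.Date(day, origin = "1970-01-01")
  d$start_min <- (d$.s - day * .MS_DAY) / .MS_MIN
  d$end_min <- d$start_min + (d$.e - d$.s) / .MS_MIN
  d$.s <- d$.e <- NULL
  d <- d[order(d$user_id, d$local_date, d$start_min), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Bin gyroscope samples into local calendar days
#'
#' @param gyro data.frame from [readGyro()].
#' @inheritParams binEventsByDay
#' @return the samples with `local_date` and `t_min` columns.
#' @export
binGyroByDay <- function(gyro, tzOffsetMinutes = 540) {
  off <- .resolveOffsets(gyro$user_id, tzOffsetMinutes)
  t <- gyro$t_utc_ms + off * .MS_MIN
  day <- floor(t / .MS_DAY)
  gyro$local_date <- as.Date(day, origin = "1970-01-01")
  gyro$t_min <- (t - day * .MS_DAY) / .MS_MIN
  gyro <- gyro[order(gyro$user_id, gyro$local_date, gyro$t_min), , drop = FALSE]
  rownames(gyro) <- NULL
  gyro
}

#' Per-user-day completeness table
#'
#' A day counts as a complete 24-hour observation window iff it is neither
#' the first nor the last calendar day of that user's observed span (edge
#' days are partially observed almost by construction).
#'
#' @param binnedEvents output of [binEventsByDay()].
#' @return data.frame with columns `user_id`, `local_date`, `complete`.
#' @export
dayTable <- function(binnedEvents) {
  key <- unique(binnedEvents[, c("user_id", "local_date")])
  key <- key[order(key$user_id, key$local_date), , drop = FALSE]
  rng <- do.call(rbind, lapply(split(key$local_date, key$user_id), range))
  first <- rng[match(key$user_id, rownames(rng)), 1L]
  last <- rng[match(key$user_id, rownames(rng)), 2L]
  key$complete <- key$local_date != first & key$local_date != last
  rownames(key) <- NULL
  key
}

.resolveOffsets <- function(userIds, tzOffsetMinutes) {
  if (is.data.frame(tzOffsetMinutes)) {
    off <- tzOffsetMinutes$tz_offset_minutes
    names(off) <- tzOffsetMinutes$user_id
    tzOffsetMinutes <- off
  }
  if (length(tzOffsetMinutes) == 1L && is.null(names(tzOffsetMinutes)))
    return(rep(as.numeric(tzOffsetMinutes), length(userIds)))
  off <- unname(tzOffsetMinutes[as.character(userIds)])
  if (anyNA(off)) stop("missing time-zone offset for some user(s)")
  as.numeric(off)
}
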