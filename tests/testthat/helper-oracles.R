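# Independent brute-force oracles, written directly from the feature and
# statistic definitions (loops and explicit formulas; no shared code with
# the implementation under test).

# non-overlapping random day: 2n sorted breakpoints become n sessions
randomDay <- function(nMax = 20, categories = 0:11, pEmpty = 0.05) {
  n <- if (runif(1) < pEmpty) 0L else sample.int(nMax, 1L)
  if (n == 0L)
    return(data.frame(start_min = numeric(0), end_min = numeric(0),
                      category = integer(0)))
  pts <- sort(runif(2 * n, 0, 1440))
  data.frame(start_min = pts[seq(1, 2 * n, 2)],
             end_min = pts[seq(2, 2 * n, 2)],
             category = sample(categories, n, replace = TRUE))
}

randomDayGyro <- function(nMax = 15) {
  n <- sample.int(nMax, 1L)
  data.frame(t_min = runif(n, 0, 1440), wx = rnorm(n), wy = rnorm(n),
             wz = rnorm(n))
}

oracleSd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

oracleFeaturizeDay <- function(ev, gy = NULL, kSd = 1,
                               upperCats = c(0L, 1L, 2L, 3L, 4L, 5L, 6L,
                                             11L)) {
  upperCats <- sort(upperCats)
  out <- c(mean_session_time = 0, total_session = 0, n_opens = 0,
           sleep = 1440, average_gap = 0)
  for (c in 0:11) out[paste0("app_time_", c)] <- 0
  for (c in 0:11) out[paste0("app_opens_", c)] <- 0
  for (c in upperCats) out[paste0("app_upper_", c)] <- 0
  ev <- ev[order(ev$start_min), , drop = FALSE]
  n <- nrow(ev)
  if (n > 0) {
    dur <- numeric(n)
    for (i in 1:n) dur[i] <- ev$end_min[i] - ev$start_min[i]
    out["mean_session_time"] <- sum(dur) / n
    out["total_session"] <- sum(dur)
    out["n_opens"] <- n
    gaps <- numeric(0)
    if (n > 1) for (i in 1:(n - 1))
      gaps <- c(gaps, max(0, ev$start_min[i + 1] - ev$end_min[i]))
    out["average_gap"] <- if (length(gaps)) sum(gaps) / length(gaps) else 0
    out["sleep"] <- max(ev$start_min[1], gaps, 1440 - ev$end_min[n])
    for (c in 0:11) {
      t <- 0; k <- 0
      for (i in 1:n) if (ev$category[i] == c) {
        t <- t + dur[i]; k <- k + 1
      }
      out[paste0("app_time_", c)] <- t
      out[paste0("app_opens_", c)] <- k
    }
    for (c in upperCats) {
      d <- dur[ev$category == c]
      if (length(d) >= 2) {
        thr <- sum(d) / length(d) + kSd * oracleSd(d)
        out[paste0("app_upper_", c)] <- sum(d > thr)
      }
    }
  }
  gf <- c(gyro_mean_activity = NA_real_, gyro_avg_gap_activity = NA_real_,
          gyro_total_activity = NA_real_)
  if (!is.null(gy) && nrow(gy)) {
    norms <- sqrt(gy$wx^2 + gy$wy^2 + gy$wz^2)
    gf["gyro_mean_activity"] <- sum(norms) / length(norms)
    gf["gyro_total_activity"] <- sum(norms)
    gapNorms <- numeric(0)
    for (j in seq_len(nrow(gy))) {
      inside <- FALSE
      for (i in seq_len(n))
        if (gy$t_min[j] >= ev$start_min[i] && gy$t_min[j] < ev$end_min[i])
          inside <- TRUE
      if (!inside) gapNorms <- c(gapNorms, norms[j])
    }
    gf["gyro_avg_gap_activity"] <- if (length(gapNorms))
      sum(gapNorms) / length(gapNorms) else 0
  }
  c(out, gf)
}

# Welch statistics straight from the formulas (y vs x, one-tailed in the
# direction of the observed difference)
oracleWelch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  mx <- sum(x) / nx; my <- sum(y) / ny
  vx <- sum((x - mx)^2) / (nx - 1); vy <- sum((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (my - mx) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- if (my >= mx) stats::pt(t, df, lower.tail = FALSE) else
    stats::pt(t, df)
  sp <- sqrt(((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2))
  list(t = t, df = df, p = p, d = abs(my - mx) / sp)
}

oraclePearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# average ranks computed by counting, then Pearson on the ranks
oracleRank <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x))
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  r
}

oracleSpearman <- function(x, y) oraclePearson(oracleRank(x), oracleRank(y))

# one-tailed permutation test for a difference in means (y vs x)
oraclePermutationP <- function(x, y, B = 4000) {
  pool <- c(x, y)
  obs <- mean(y) - mean(x)
  hits <- 0
  for (b in seq_len(B)) {
    idx <- sample(length(pool), length(y))
    d <- mean(pool[idx]) - mean(pool[-idx])
    if (obs >= 0 && d >= obs) hits <- hits + 1
    if (obs < 0 && d <= obs) hits <- hits + 1
  }
  hits / B
}
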