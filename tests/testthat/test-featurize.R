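# Daily digital biomarkers.

test_that("worked example: three sessions, gap and sleep conventions", {
  ev <- data.frame(start_min = c(600, 610, 1200),
                   end_min = c(602, 614, 1203),
                   category = 3L)
  f <- featurizeDay(ev)
  expect_equal(unname(f["n_opens"]), 3)
  expect_equal(unname(f["total_session"]), 9)
  expect_equal(unname(f["mean_session_time"]), 3)
  expect_equal(unname(f["average_gap"]), mean(c(8, 586)))
  expect_equal(unname(f["sleep"]), 600)  # midnight-to-first-open gap wins
  expect_equal(unname(f["app_opens_3"]), 3)
  expect_equal(unname(f["app_time_3"]), 9)
})

test_that("empty day: zero counts, full-day sleep", {
  f <- featurizeDay(data.frame(start_min = numeric(0),
                               end_min = numeric(0), category = integer(0)))
  expect_equal(unname(f["n_opens"]), 0)
  expect_equal(unname(f["total_session"]), 0)
  expect_equal(unname(f["mean_session_time"]), 0)
  expect_equal(unname(f["average_gap"]), 0)
  expect_equal(unname(f["sleep"]), 1440)
})

test_that("the nonsensor layout has exactly 37 features", {
  expect_length(featureLayout(gyro = FALSE), 37L)
  expect_length(featureLayout(gyro = TRUE), 40L)
  expect_length(featureLayout(upperCategories = c(0, 3), gyro = FALSE), 31L)
})

test_that("upper session counts follow the mean + k*SD rule", {
  ev <- data.frame(start_min = c(0, 20, 40, 60),
                   end_min = c(1, 21, 41, 70), category = 2L)
  # durations 1,1,1,10: mean 3.25, sd 4.5; only 10 exceeds mean + 1 SD
  expect_equal(upperSessionCount(ev, 2L, kSd = 1), 1L)
  # all equal durations: zero spread, count 0
  evEq <- data.frame(start_min = c(0, 10, 20), end_min = c(2, 12, 22),
                     category = 5L)
  expect_equal(upperSessionCount(evEq, 5L, kSd = 1), 0L)
  # k = 0 counts sessions strictly above the mean
  expect_equal(upperSessionCount(ev, 2L, kSd = 0), 1L)
  ev2 <- data.frame(start_min = c(0, 10, 20), end_min = c(1, 12, 25),
                    category = 1L)  # durations 1, 2, 5; mean 8/3
  expect_equal(upperSessionCount(ev2, 1L, kSd = 0), 1L)
  expect_error(upperSessionCount(ev, 99L), "unknown")
  expect_equal(upperSessionCount(ev, 7L), 0L)  # no events in category
})

test_that("gyro features: norms, gap samples, empty stream", {
  ev <- data.frame(start_min = 100, end_min = 200, category = 1L)
  gy <- data.frame(t_min = 50, wx = 3, wy = 4, wz = 0)  # in a gap
  f <- gyroFeatures(gy, ev)
  expect_equal(unname(f), c(5, 5, 5))
  gyIn <- data.frame(t_min = 150, wx = 0, wy = 0, wz = 2)  # during usage
  f2 <- gyroFeatures(gyIn, ev)
  expect_equal(unname(f2["gyro_avg_gap_activity"]), 0)
  zero <- data.frame(t_min = c(10, 500), wx = 0, wy = 0, wz = 0)
  expect_equal(unname(gyroFeatures(zero, ev)), c(0, 0, 0))
  expect_true(all(is.na(gyroFeatures(NULL, ev))))
})

test_that("features match the brute-force oracle on random days", {
  set.seed(101)
  for (i in 1:60) {
    ev <- randomDay()
    gy <- randomDayGyro()
    expect_equal(featurizeDay(ev, gy), oracleFeaturizeDay(ev, gy))
  }
})

test_that("doubling durations doubles times but not counts", {
  set.seed(5)
  pts <- sort(runif(16, 0, 700))  # doubled durations stay inside the day
  ev <- data.frame(start_min = pts[seq(1, 15, 2)],
                   end_min = pts[seq(2, 16, 2)],
                   category = sample(0:11, 8, TRUE))
  ev2 <- ev
  ev2$end_min <- ev$start_min + 2 * (ev$end_min - ev$start_min)
  f1 <- featurizeDay(ev); f2 <- featurizeDay(ev2)
  expect_equal(unname(f2["total_session"]), 2 * unname(f1["total_session"]))
  expect_equal(unname(f2["mean_session_time"]),
               2 * unname(f1["mean_session_time"]))
  expect_equal(unname(f2["n_opens"]), unname(f1["n_opens"]))
})

test_that("featurize assembles a valid experiment with completeness flags", {
  sim <- simulateCohort(defaultProfiles()["none"], nUsers = 2L,
                        nDaysPerUser = 3L, seed = 9L)
  ev <- readEvents(sim$events, sim$categories)
  dpe <- featurize(binEventsByDay(ev, 540), binGyroByDay(sim$gyro, 540))
  expect_s4_class(dpe, "DigitalPhenotypeExperiment")
  expect_true(validObject(dpe))
  expect_equal(ncol(dpe), 10L)            # 2 users x (3 + 2 edge) days
  expect_equal(sum(dayInfo(dpe)$complete), 6L)
  m <- featureMatrix(dpe)
  expect_equal(unname(m["n_opens", ]),
               unname(colSums(m[paste0("app_opens_", 0:11), ])))
  expect_true(all(m["total_session", ] <= 1440))
})
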