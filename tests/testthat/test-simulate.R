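# The synthetic event-stream generator.

test_that("profiles validate and derive their internal parameters", {
  p <- cohortProfile("severe")
  expect_equal(sum(p$categoryWeights), 1)
  expect_gt(p$gyroUsageActivity, p$gyroGapActivity)
  expect_gt(p$nGyroSamples, 0)
  # truncated-normal location correction keeps the sleep mean on target
  m <- integrate(function(x) x * dnorm(x, p$sleepMu, p$sleepSd),
                 p$sleepLo, p$sleepHi)$value /
    diff(pnorm(c(p$sleepLo, p$sleepHi), p$sleepMu, p$sleepSd))
  expect_equal(m, p$sleepMean, tolerance = 1e-6)
  over <- cohortProfile("none", nOpens = 100)
  expect_equal(over$nOpens, 100)
})

test_that("simulated days are well-formed and sleep matches the window", {
  set.seed(77)
  p <- cohortProfile("none")
  for (i in 1:10) {
    d <- simulateUserDay(p)
    ev <- d$events
    expect_true(all(ev$start_min >= 0 & ev$end_min <= 1440))
    expect_true(all(diff(ev$start_min) >= 0))
    expect_true(all(ev$end_min >= ev$start_min))
    f <- featurizeDay(ev, d$gyro)
    # the nocturnal window at the day start is the longest gap
    expect_equal(unname(f["sleep"]), ev$start_min[1], tolerance = 1e-8)
    expect_gte(unname(f["sleep"]), 120)
  }
})

test_that("corpus moments recover the profile targets", {
  set.seed(99)
  for (lab in c("none", "severe")) {
    p <- cohortProfile(lab)
    f <- vapply(1:600, function(i) {
      d <- simulateUserDay(p)
      featurizeDay(d$events, d$gyro)
    }, numeric(40))
    expect_equal(mean(f["mean_session_time", ]), p$meanSessionTime,
                 tolerance = 0.10)
    expect_equal(mean(f["n_opens", ]), p$nOpens, tolerance = 0.10)
    expect_equal(mean(f["sleep", ]), p$sleepMean, tolerance = 0.10)
    expect_equal(mean(f["gyro_avg_gap_activity", ]), p$gyroGapActivity,
                 tolerance = 0.15)
    # opens share of the messaging category follows the mixture weight
    expect_equal(mean(f["app_opens_3", ]) / mean(f["n_opens", ]),
                 p$categoryWeights[4], tolerance = 0.10)
  }
})

test_that("severe days show higher gap activity than none days", {
  set.seed(15)
  gap <- function(lab) {
    p <- cohortProfile(lab)
    mean(vapply(1:80, function(i) {
      d <- simulateUserDay(p)
      unname(featurizeDay(d$events, d$gyro)["gyro_avg_gap_activity"])
    }, 0))
  }
  expect_gt(gap("severe"), gap("none"))
})

test_that("PHQ-9 draws respect the profile band and subscale pinning", {
  set.seed(3)
  for (i in 1:20) {
    rn <- simulatePhq9(cohortProfile("none"))
    expect_lt(rn$total, 5)
    expect_equal(rn$affective_269, 0L)
    rs <- simulatePhq9(cohortProfile("severe"))
    expect_gte(rs$total, 20)
    expect_equal(rs$affective_269, 9L)
  }
})

test_that("identical seeds give identical cohorts, different seeds differ", {
  a <- simulateCohort(defaultProfiles()["none"], nUsers = 2L,
                      nDaysPerUser = 2L, seed = 42L)
  b <- simulateCohort(defaultProfiles()["none"], nUsers = 2L,
                      nDaysPerUser = 2L, seed = 42L)
  expect_identical(a$events, b$events)
  expect_identical(a$gyro, b$gyro)
  expect_identical(a$phq9, b$phq9)
  c <- simulateCohort(defaultProfiles()["none"], nUsers = 2L,
                      nDaysPerUser = 2L, seed = 43L)
  expect_false(identical(a$events, c$events))
})

test_that("written CSVs round-trip through the ingest readers", {
  dir <- tempfile()
  sim <- simulateCohort(defaultProfiles()["severe"], nUsers = 2L,
                        nDaysPerUser = 2L, seed = 8L, outDir = dir)
  ev <- readEvents(file.path(dir, "events.csv"),
                   readCategoryMap(file.path(dir, "categories.yaml")))
  expect_equal(nrow(ev), nrow(sim$events))
  expect_equal(nrow(readGyro(file.path(dir, "gyro.csv"))), nrow(sim$gyro))
  expect_equal(readPhq9(file.path(dir, "phq9.csv"))$total, sim$phq9$total)
  expect_equal(readUsers(file.path(dir, "users.csv"))$user_id,
               sim$users$user_id)
  unlink(dir, recursive = TRUE)
})

test_that("zero-activity gyro profile yields zero activity features", {
  p <- cohortProfile("none", gyroMeanActivity = 0, gyroGapActivity = 0,
                     gyroTotalActivity = 0)
  set.seed(1)
  d <- simulateUserDay(p)
  expect_null(d$gyro)  # no informative samples to emit
})

test_that("days-per-user draws are truncated at one day", {
  sim <- simulateCohort(defaultProfiles()["none"], nUsers = 15L,
                        nDaysPerUser = NULL, seed = 31L, gyro = FALSE)
  b <- binEventsByDay(readEvents(sim$events, sim$categories), 540)
  nDays <- table(unique(b[, c("user_id", "local_date")])$user_id)
  expect_true(all(nDays >= 3))  # >= 1 complete day + 2 edge days
})
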