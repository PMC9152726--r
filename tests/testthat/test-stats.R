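# Welch comparisons, Cohen's d, correlations, and summary tables.

test_that("Welch t, df, p and Cohen's d match the formula oracle", {
  set.seed(31)
  for (i in 1:25) {
    x <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, .5, 3))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, .5, 3))
    got <- compareFeature(x, y)
    want <- oracleWelch(x, y)
    expect_equal(got$t, want$t)
    expect_equal(got$df, want$df)
    expect_equal(got$p, want$p)
    expect_equal(got$cohen_d, want$d)
  }
})

test_that("identical cohorts give d = 0; degenerate case gives p = 0.5", {
  x <- c(1, 2, 3, 4)
  expect_equal(compareFeature(x, x)$cohen_d, 0)
  z <- rep(2, 5)
  deg <- compareFeature(z, z)
  expect_equal(deg$p, 0.5)
  expect_equal(deg$cohen_d, 0)
})

test_that("d magnitude is antisymmetric in cohort order and ~1 at unit shift", {
  set.seed(7)
  x <- rnorm(1e4); y <- rnorm(1e4, 1)
  ab <- compareFeature(x, y); ba <- compareFeature(y, x)
  expect_equal(ab$cohen_d, ba$cohen_d)
  expect_equal(ab$direction, "greater")
  expect_equal(ba$direction, "less")
  expect_equal(ab$cohen_d, 1, tolerance = 0.05)
  expect_lt(ab$p, 1e-10)
})

test_that("one-tailed Welch p agrees with a permutation test at n = 30", {
  set.seed(13)
  x <- rnorm(30); y <- rnorm(30, 0.4)
  pW <- compareFeature(x, y)$p
  pPerm <- oraclePermutationP(x, y, B = 4000)
  expect_lt(abs(pW - pPerm), 0.01)  # ~3x the Monte-Carlo SD at B = 4000
})

test_that("correlations match brute-force Pearson/Spearman oracles", {
  set.seed(41)
  rec <- simulateReferencePhq9(seed = 2L)[1:40, ]
  mh <- setNames(runif(40, 0, 100), rec$user_id)
  got <- itemMhssCorrelation(rec, mh, items = c(2, 6, 9))
  v <- rec$q2 + rec$q6 + rec$q9
  expect_equal(got$pearson_r, oraclePearson(v, unname(mh)))
  expect_equal(got$spearman_rho, oracleSpearman(v, unname(mh)))
  expect_equal(got$label, "q2+q6+q9")
  # Spearman equals Pearson on ranks (tie-aware), property over draws
  for (i in 1:10) {
    a <- sample(0:5, 25, TRUE); b <- sample(0:5, 25, TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    expect_equal(cor(a, b, method = "spearman"),
                 oraclePearson(oracleRank(a), oracleRank(b)))
  }
})

test_that("perfectly monotone pairings give rho = +/-1", {
  rec <- simulateReferencePhq9(seed = 3L)
  rec <- rec[!duplicated(rec$total), ][1:10, ]
  mh <- setNames(as.numeric(rec$total) * 3 + 1, rec$user_id)
  r <- itemMhssCorrelation(rec, mh, items = 1:9)
  expect_equal(r$pearson_r, 1)
  expect_equal(r$spearman_rho, 1)
  anti <- setNames(100 - as.numeric(rec$total), rec$user_id)
  expect_equal(itemMhssCorrelation(rec, anti, items = 1:9)$spearman_rho, -1)
})

test_that("zero variance flags the correlation as undefined", {
  rec <- simulateReferencePhq9(seed = 5L)[1:10, ]
  mh <- setNames(rep(50, 10), rec$user_id)
  expect_warning(r <- itemMhssCorrelation(rec, mh, items = 2), "zero variance")
  expect_true(is.na(r$pearson_r))
})

test_that("cohort tables reproduce the reference demographic arithmetic", {
  demo <- referenceDemographics()
  phq9 <- simulateReferencePhq9(seed = 6L)
  users <- data.frame(
    user_id = phq9$user_id,
    age_bracket = rep(names(demo$age), times = demo$age),
    gender = rep(names(demo$gender), times = demo$gender),
    language = rep(names(demo$language), times = demo$language),
    tz_offset_minutes = 540L)
  tab <- cohortTables(users, phq9)
  expect_equal(tab$n, 558L)
  expect_equal(tab$age$pct[tab$age$value == "18-25"], 84.9)
  expect_equal(tab$gender$pct[tab$gender$value == "female"], 51.3)
  expect_equal(tab$language$pct[tab$language$value == "korean"], 87.3)
  expect_equal(tab$band$n, c(63L, 124L, 162L, 134L, 75L))
})

test_that("single-user tables have all-or-nothing percentages", {
  phq9 <- scorePhq9(rep(2L, 9), userId = "solo")
  users <- data.frame(user_id = "solo", age_bracket = "18-25",
                      gender = "female", language = "korean",
                      tz_offset_minutes = 540L)
  tab <- cohortTables(users, phq9)
  expect_true(all(tab$band$pct %in% c(0, 100)))
})

test_that("compareCohorts ranks features by effect size over observations", {
  obs <- toyObservations(nU = 8, nD = 4, shift = 3, seed = 12)
  cmp <- compareCohorts(obs, "none", "severe")
  expect_true(all(diff(cmp$cohen_d) <= 0))
  # the six shifted features carry the largest effects
  expect_true(all(rownames(featureMatrix(obs))[1:6] %in% cmp$feature[1:8]))
  expect_true(all(cmp$p >= 0 & cmp$p <= 1))
})
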