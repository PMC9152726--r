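# Classifiers, the MHSS, and majority-of-days verdicts.

test_that("perfectly separable classes reach 100% on every metric", {
  obs <- toyObservations(nU = 8, nD = 4, shift = 8, seed = 3)
  rep <- trainAndEvaluate(obs, "random_forest", nBoot = 1L, seed = 1L,
                          ntree = 100,
                          splitPlan = makeSplitPlan(obs, nFolds = 4L,
                                                    seed = 1L))
  expect_equal(accuracy(rep), 100)
  expect_equal(perClassMetrics(rep)$f1, c(100, 100))
})

test_that("permuted labels give chance-level binary accuracy", {
  obs <- toyObservations(nU = 30, nD = 4, shift = 0, seed = 8)
  rep <- trainAndEvaluate(obs, "random_forest", nBoot = 1L, seed = 2L,
                          ntree = 150,
                          splitPlan = makeSplitPlan(obs, nFolds = 6L,
                                                    seed = 2L))
  expect_gt(accuracy(rep), 35)
  expect_lt(accuracy(rep), 65)
})

test_that("all three algorithms produce valid reports", {
  obs <- toyObservations(nU = 6, nD = 3, shift = 4, seed = 5)
  plan <- makeSplitPlan(obs, nFolds = 3L, seed = 1L)
  for (alg in c("random_forest", "gradient_boosting", "svm_rbf")) {
    rep <- trainAndEvaluate(obs, alg, splitPlan = plan, nBoot = 1L,
                            seed = 1L, ntree = 60, nrounds = 20)
    expect_s4_class(rep, "ModelReport")
    expect_true(validObject(rep))
    expect_gte(accuracy(rep), 0)
    expect_lte(accuracy(rep), 100)
  }
})

test_that("random forest Gini importances are normalized and ordered", {
  obs <- toyObservations(nU = 6, nD = 3, shift = 4, seed = 6)
  rep <- trainAndEvaluate(obs, "random_forest", nBoot = 1L, seed = 1L,
                          ntree = 100,
                          splitPlan = makeSplitPlan(obs, nFolds = 3L,
                                                    seed = 1L))
  imp <- importances(rep)
  expect_equal(sum(imp), 1)
  expect_true(all(diff(imp) <= 0))
  expect_true(all(imp >= 0))
})

test_that("MHSS is 100 x the depression-class probability, in [0,100]", {
  obs <- toyObservations(nU = 8, nD = 4, shift = 6, seed = 9)
  rep <- trainAndEvaluate(obs, "random_forest", nBoot = 1L, seed = 1L,
                          ntree = 100,
                          splitPlan = makeSplitPlan(obs, nFolds = 4L,
                                                    seed = 1L))
  s <- mhssScore(rep, obs)
  expect_true(all(s >= 0 & s <= 100))
  lab <- dayInfo(obs)$label
  expect_gt(mean(s[lab == "severe"]), mean(s[lab == "none"]))
  # missing feature columns are named in the error
  crippled <- obs[-(1:2), ]
  expect_error(mhssScore(rep, crippled), "mean_session_time")
})

test_that("majority verdicts follow the strict-majority rule", {
  d <- as.Date("2021-11-01")
  expect_equal(majorityVerdict(MhssSeries("u", d + 0:2, c(60, 70, 40))),
               "depressed")
  expect_equal(majorityVerdict(MhssSeries("u", d + 0:2, c(10, 20, 30))),
               "not_depressed")
  expect_equal(majorityVerdict(MhssSeries("u", d + 0:1, c(60, 40))), "tie")
  expect_equal(majorityVerdict(MhssSeries("u", d, 50)), "tie")
  expect_error(majorityVerdict(MhssSeries("u", d[0], numeric(0))), "empty")
  # verdict invariant to day order (dates sort on construction)
  expect_equal(majorityVerdict(MhssSeries("u", d + c(2, 0, 1),
                                          c(40, 60, 70))), "depressed")
})

test_that("weekly verdicts split the series into 7-day windows", {
  d <- as.Date("2021-11-01")
  s <- MhssSeries("u", d + 0:13, c(rep(80, 7), rep(20, 7)))
  w <- majorityVerdict(s, window = "weekly")
  expect_equal(nrow(w), 2L)
  expect_equal(w$verdict, c("depressed", "not_depressed"))
  expect_equal(w$n_days, c(7L, 7L))
})

test_that("high-day fractions pool days within each band", {
  mk <- function(id, v) MhssSeries(id, as.Date("2021-11-01") +
                                     seq_along(v) - 1, v)
  sl <- list(mk("a", c(60, 40)), mk("b", c(90, 90, 90)), mk("c", c(10, 80)))
  bands <- c(a = "none", b = "severe", c = "none")
  hdf <- highDayFraction(sl, bands)
  expect_equal(hdf$pct_high[hdf$band == "none"], 50)    # 2 of 4 days
  expect_equal(hdf$pct_high[hdf$band == "severe"], 100)
  expect_equal(hdf$n_days, c(4L, 3L))
  all100 <- highDayFraction(list(mk("a", 90), mk("b", 70)),
                            c(a = "none", b = "severe"))
  expect_true(all(all100$pct_high == 100))
})
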