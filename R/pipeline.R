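# Pipeline orchestration: one config object, one entry point running
# simulate/ingest -> featurize -> cohort -> classify -> stats.

#' Default pipeline configuration
#'
#' Every constant with a study-stated value defaults to that value: PHQ-9
#' band edges (5/10/15/20), the MHSS cutoff (50), 15-fold cross-validation,
#' the 1-SD long-session threshold, and majority-class undersampling.
#'
#' @return nested list of configuration values.
#' @export
defaultPipelineConfig <- function() {
  list(
    paths = list(events = NULL, gyro = NULL, phq9 = NULL, users = NULL,
                 categories = NULL),
    simulate = list(enabled = TRUE, profiles = c("none", "severe"),
                    n_users = 50L, n_days_per_user = 10L),
    features = list(k_sd = 1,
                    upper_categories = c(0L, 1L, 2L, 3L, 4L, 5L, 6L, 11L)),
    task = "binary",
    algorithm = "random_forest",
    mhss_cutoff = 50,
    n_folds = 15L,
    n_boot = 15L,
    balance_mode = "under",
    grouped_folds = TRUE,
    ntree = 500,
    seed = 1L
  )
}

#' Read and validate a pipeline configuration
#'
#' @param path YAML file; values override [defaultPipelineConfig()].
#' @return validated config list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- defaultPipelineConfig()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  validatePipelineConfig(cfg)
}

#' @rdname readPipelineConfig
#' @param cfg a configuration list.
#' @export
validatePipelineConfig <- function(cfg) {
  if (!cfg$task %in% c("binary", "three_class", "questions", "gyro_binary"))
    stop("unknown task: ", cfg$task)
  if (!cfg$algorithm %in% c("random_forest", "gradient_boosting", "svm_rbf"))
    stop("unknown algorithm: ", cfg$algorithm)
  if (!cfg$balance_mode %in% c("under", "over"))
    stop("unknown balance mode: ", cfg$balance_mode)
  stopifnot(cfg$n_folds >= 2, cfg$n_boot >= 1, cfg$features$k_sd >= 0,
            cfg$mhss_cutoff > 0, cfg$mhss_cutoff < 100)
  cfg
}

#' Run the full pipeline
#'
#' Either simulates a study (when `cfg$simulate$enabled`) or reads the four
#' raw input files, then featurizes days, builds and balances labeled
#' observations, cross-validates the configured classifier, scores every
#' complete day with the MHSS, takes majority-of-days verdicts, and runs
#' the cohort statistics. Row/observation counts of every stage are
#' reported via `message()`.
#'
#' @param cfg configuration from [readPipelineConfig()] /
#'   [defaultPipelineConfig()].
#' @param seed overrides `cfg$seed` when given.
#' @param outDir when given, writes `model_report.json`, `mhss.csv`,
#'   `importances.csv` and `stats_report.json` there.
#' @return list with elements `dpe`, `observations`, `report`
#'   ([ModelReport]), `mhss` (list of [MhssSeries]), `verdicts`,
#'   `high_day_fraction`, `comparisons`, `tables`.
#' @export
runPipeline <- function(cfg = defaultPipelineConfig(), seed = NULL,
                        outDir = NULL) {
  cfg <- validatePipelineConfig(cfg)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  stage <- function(name, expr) {
    r <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    r
  }
  sim <- NULL
  if (isTRUE(cfg$simulate$enabled)) {
    sim <- stage("simulate", {
      profs <- defaultProfiles()[cfg$simulate$profiles]
      simulateCohort(profs, nUsers = cfg$simulate$n_users,
                     nDaysPerUser = cfg$simulate$n_days_per_user,
                     seed = cfg$seed)
    })
    catMap <- sim$categories
    events <- stage("ingest", readEvents(sim$events, catMap))
    gyroRaw <- if (!is.null(sim$gyro)) readGyro(sim$gyro)
    phq9 <- readPhq9(sim$phq9)
    users <- readUsers(sim$users)
  } else {
    catMap <- stage("ingest", readCategoryMap(cfg$paths$categories))
    events <- stage("ingest", readEvents(cfg$paths$events, catMap))
    gyroRaw <- if (!is.null(cfg$paths$gyro)) readGyro(cfg$paths$gyro)
    phq9 <- stage("ingest", readPhq9(cfg$paths$phq9))
    users <- stage("ingest", readUsers(cfg$paths$users))
  }
  message("ingest: ", nrow(events), " events, ", nrow(phq9), " PHQ-9 records, ",
          nrow(users), " users")
  binned <- stage("bin", binEventsByDay(events, users))
  gyroBinned <- if (!is.null(gyroRaw))
    stage("bin", binGyroByDay(gyroRaw, users))
  dpe <- stage("featurize",
               featurize(binned, gyroBinned, kSd = cfg$features$k_sd,
                         upperCategories = cfg$features$upper_categories))
  message("featurize: ", ncol(dpe), " user-days (",
          sum(colData(dpe)$complete), " complete)")
  obs <- stage("cohort", buildObservations(dpe, phq9, task = cfg$task,
                                           users = users))
  bal <- stage("cohort", balanceClasses(obs, seed = cfg$seed,
                                        mode = cfg$balance_mode))
  message("cohort: ", ncol(obs), " observations, ", ncol(bal),
          " after balancing")
  plan <- makeSplitPlan(bal, nFolds = cfg$n_folds,
                        grouped = cfg$grouped_folds, seed = cfg$seed)
  report <- stage("classify",
                  trainAndEvaluate(bal, algorithm = cfg$algorithm,
                                   splitPlan = plan, nBoot = cfg$n_boot,
                                   seed = cfg$seed, ntree = cfg$ntree))
  message(sprintf("classify: accuracy %.1f%%", accuracy(report)))
  series <- stage("score", mhssSeries(report, dpe))
  verdicts <- vapply(series, majorityVerdict, "",
                     cutoff = cfg$mhss_cutoff)
  bands <- stats::setNames(as.character(phq9$band), phq9$user_id)
  series2 <- series[names(series) %in% names(bands)]
  hdf <- stage("validate",
               highDayFraction(series2, bands, cutoff = cfg$mhss_cutoff))
  comparisons <- if (cfg$task %in% c("binary", "gyro_binary"))
    stage("stats", compareCohorts(obs)) else NULL
  tables <- stage("stats", cohortTables(users, phq9))
  res <- list(dpe = dpe, observations = bal, report = report,
              mhss = series, verdicts = verdicts,
              high_day_fraction = hdf, comparisons = comparisons,
              tables = tables, config = cfg)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(list(
      task = report@task, algorithm = report@algorithm,
      accuracy = accuracy(report), accuracy_sd = report@accuracySd,
      per_class = perClassMetrics(report)),
      file.path(outDir, "model_report.json"), auto_unbox = TRUE, digits = NA)
    mh <- do.call(rbind, lapply(res$mhss, function(s)
      data.frame(user_id = s@userId, date = s@dates, mhss = s@scores)))
    utils::write.csv(mh, file.path(outDir, "mhss.csv"), row.names = FALSE)
    if (length(importances(report)))
      utils::write.csv(data.frame(feature = names(importances(report)),
                                  importance = importances(report)),
                       file.path(outDir, "importances.csv"),
                       row.names = FALSE)
    jsonlite::write_json(list(high_day_fraction = hdf,
                              band = tables$band),
                         file.path(outDir, "stats_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
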