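# Day-level depression classifiers and the MHSS. Algorithms run on library
# defaults (random forest with 500 trees); no tuning is performed.

.fitOne <- function(algorithm, x, y, ntree = 500, nrounds = 100) {
  switch(algorithm,
    random_forest = randomForest::randomForest(x = x, y = y, ntree = ntree),
    gradient_boosting = {
      fit <- xgboost::xgboost(x, y, nrounds = nrounds, verbosity = 0)
      list(fit = fit, levels = levels(y), k = nlevels(y))
    },
    # scale = FALSE: the pipeline has no feature-standardization stage, so
    # the SVM must not add one silently; RBF kernels then see the raw
    # minutes/counts scales, exactly as an untuned SVC would
    svm_rbf = e1071::svm(x = x, y = y, kernel = "radial",
                         probability = TRUE, scale = FALSE),
    stop("unknown algorithm: ", algorithm))
}

# class-probability matrix (columns = factor levels) from a fitted model
.predictProb <- function(algorithm, fit, x) {
  switch(algorithm,
    random_forest = stats::predict(fit, x, type = "prob"),
    gradient_boosting = {
      p <- stats::predict(fit$fit, x, type = "response")
      if (is.matrix(p)) p[, fit$levels, drop = FALSE]
      else {
        # binary: the vector is P(second factor level)
        m <- cbind(1 - p, p)
        colnames(m) <- fit$levels
        m
      }
    },
    svm_rbf = {
      p <- attr(stats::predict(fit, x, probability = TRUE), "probabilities")
      p[, fit$levels, drop = FALSE]
    })
}

.metricsFromConfusion <- function(truth, pred, classes) {
  tab <- table(factor(truth, classes), factor(pred, classes))
  prec <- 100 * diag(tab) / pmax(colSums(tab), 1)
  rec <- 100 * diag(tab) / pmax(rowSums(tab), 1)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(accuracy = 100 * sum(diag(tab)) / sum(tab),
       perClass = data.frame(class = classes, precision = unname(prec),
                             recall = unname(rec), f1 = unname(f1)))
}

#' Train and cross-validate a day-level classifier
#'
#' Runs the chosen algorithm under the split plan's k-fold cross-validation,
#' optionally repeated over bootstrap resamples of the observation set, and
#' aggregates per-fold accuracy and per-class precision/recall/F1 as means
#' (SD retained for accuracy). Folds whose training or test part collapses
#' to a single class are skipped with a warning. A final model is refit on
#' all observations and kept for scoring; for random forests its Gini (mean
#' decrease in impurity) importances, normalized to sum to 1, are reported
#' in decreasing order.
#'
#' @param obs balanced labeled observations (see [balanceClasses()]).
#' @param algorithm `"random_forest"`, `"gradient_boosting"` or
#'   `"svm_rbf"`.
#' @param splitPlan a [SplitPlan]; built with defaults when `NULL`.
#' @param nBoot bootstrap repeats of the cross-validation (default 15);
#'   `nBoot = 1` runs plain k-fold CV on the observations as given.
#' @param seed RNG seed for model fitting and bootstrap draws.
#' @param ntree random forest trees (default 500).
#' @param nrounds gradient boosting rounds (default 100).
#' @param dropGyro drop the three gyroscope rows from the design matrix
#'   (default `TRUE` except for the `gyro_binary` task, where the sensor
#'   features are the point).
#' @return a [ModelReport].
#' @export
trainAndEvaluate <- function(obs,
                             algorithm = c("random_forest",
                                           "gradient_boosting", "svm_rbf"),
                             splitPlan = NULL, nBoot = 15L, seed = 1L,
                             ntree = 500, nrounds = 100, dropGyro = NULL) {
  algorithm <- match.arg(algorithm)
  lab <- colData(obs)$label
  if (is.null(lab) || nlevels(droplevels(lab)) < 2L)
    stop("need labeled observations with >= 2 classes")
  task <- .taskOf(lab)
  if (is.null(dropGyro)) dropGyro <- task != "gyro_binary"
  x <- t(assay(obs, "features"))
  if (dropGyro)
    x <- x[, !grepl("^gyro_", colnames(x)), drop = FALSE]
  if (anyNA(x)) {
    bad <- colnames(x)[colSums(is.na(x)) > 0]
    stop("missing feature values in: ", paste(bad, collapse = ", "))
  }
  y <- droplevels(lab)
  classes <- levels(y)
  if (is.null(splitPlan)) splitPlan <- makeSplitPlan(obs, seed = seed)
  foldRows <- list()
  .withSeed(seed, {
    for (b in seq_len(nBoot)) {
      idx <- if (nBoot > 1L)
        sample(nrow(x), nrow(x), replace = TRUE) else seq_len(nrow(x))
      fold <- splitPlan@fold[idx]
      for (f in sort(unique(fold))) {
        tr <- idx[fold != f]
        te <- idx[fold == f]
        if (length(unique(y[tr])) < 2L || !length(te)) {
          warning("degenerate fold skipped (single class)")
          next
        }
        fit <- .fitOne(algorithm, x[tr, , drop = FALSE], droplevels(y[tr]),
                       ntree = ntree, nrounds = nrounds)
        prob <- .predictProb(algorithm, fit, x[te, , drop = FALSE])
        pred <- colnames(prob)[max.col(prob, ties.method = "first")]
        m <- .metricsFromConfusion(y[te], pred, classes)
        foldRows[[length(foldRows) + 1L]] <-
          cbind(data.frame(boot = b, fold = f, accuracy = m$accuracy),
                stats::setNames(as.list(c(t(as.matrix(
                  m$perClass[, c("precision", "recall", "f1")])))),
                  paste(rep(classes, each = 3),
                        c("precision", "recall", "f1"), sep = ".")))
      }
    }
  })
  if (!length(foldRows)) stop("all folds degenerate; cannot evaluate")
  fm <- do.call(rbind, foldRows)
  perClass <- data.frame(
    class = classes,
    precision = vapply(classes, function(cl)
      mean(fm[[paste0(cl, ".precision")]], na.rm = TRUE), 0),
    recall = vapply(classes, function(cl)
      mean(fm[[paste0(cl, ".recall")]], na.rm = TRUE), 0),
    f1 = vapply(classes, function(cl)
      mean(fm[[paste0(cl, ".f1")]], na.rm = TRUE), 0),
    row.names = NULL)
  final <- .withSeed(seed + 1L,
                     .fitOne(algorithm, x, y, ntree = ntree,
                             nrounds = nrounds))
  imp <- numeric(0)
  if (algorithm == "random_forest") {
    gi <- final$importance[, "MeanDecreaseGini"]
    imp <- sort(gi / sum(gi), decreasing = TRUE)
  }
  new("ModelReport", task = task, algorithm = algorithm,
      accuracy = mean(fm$accuracy), accuracySd = stats::sd(fm$accuracy),
      perClass = perClass, importance = imp,
      positiveClass = .positiveClass(classes),
      model = list(algorithm = algorithm, fit = final),
      featureNames = colnames(x),
      foldMetrics = fm[, c("boot", "fold", "accuracy")])
}

.taskOf <- function(lab) {
  lv <- levels(droplevels(lab))
  if (setequal(lv, c("none", "depression_symptoms"))) "questions"
  else if (setequal(lv, c("none", "moderate", "severe"))) "three_class"
  else "binary"
}

.positiveClass <- function(classes) {
  for (cand in c("severe", "depression_symptoms", "depressed"))
    if (cand %in% classes) return(cand)
  classes[length(classes)]
}

#' Daily Mental Health Similarity Score
#'
#' The MHSS of a day is 100 times the trained binary model's predicted
#' probability that the day belongs to the depression class, i.e. how
#' similar the day's digital behavior is to that of users screening
#' positive for depression.
#'
#' @param report a [ModelReport] from a binary task.
#' @param dpe a [DigitalPhenotypeExperiment] of days to score.
#' @return numeric vector of MHSS values in [0, 100], one per column of
#'   `dpe`.
#' @export
mhssScore <- function(report, dpe) {
  x <- t(assay(dpe, "features"))
  miss <- setdiff(report@featureNames, colnames(x))
  if (length(miss))
    stop("days lack feature(s): ", paste(miss, collapse = ", "))
  x <- x[, report@featureNames, drop = FALSE]
  if (anyNA(x)) {
    bad <- colnames(x)[colSums(is.na(x)) > 0]
    stop("missing feature values in: ", paste(bad, collapse = ", "))
  }
  prob <- .predictProb(report@model$algorithm, report@model$fit, x)
  100 * unname(prob[, report@positiveClass])
}

#' Per-user MHSS series
#'
#' Scores every complete day and collects the results per user as
#' [MhssSeries] objects.
#'
#' @inheritParams mhssScore
#' @param completeOnly score only complete days (default).
#' @return named list of [MhssSeries], one element per user.
#' @export
mhssSeries <- function(report, dpe, completeOnly = TRUE) {
  if (completeOnly) dpe <- dpe[, colData(dpe)$complete]
  s <- mhssScore(report, dpe)
  cd <- colData(dpe)
  lapply(split(seq_along(s), cd$user_id), function(i)
    MhssSeries(cd$user_id[i[1L]], cd$local_date[i], s[i]))
}

#' Pooled fraction of high-MHSS days per severity band
#'
#' For each PHQ-9 band, the percentage of all member users' scored days
#' whose MHSS exceeds the cutoff. Days are pooled across users (users with
#' more days weigh more), matching how progression validation summarises
#' day-level scores per group.
#'
#' @param seriesList list of [MhssSeries] from [mhssSeries()].
#' @param userBands named character vector, user id -> band label.
#' @param cutoff MHSS threshold (default 50).
#' @return data.frame with columns `band`, `n_users`, `n_days`,
#'   `pct_high`.
#' @export
highDayFraction <- function(seriesList, userBands, cutoff = 50) {
  ids <- vapply(seriesList, function(s) s@userId, "")
  band <- unname(userBands[ids])
  if (anyNA(band)) stop("missing band for some user(s)")
  res <- lapply(split(seriesList, band), function(g) {
    s <- unlist(lapply(g, scores))
    data.frame(n_users = length(g), n_days = length(s),
               pct_high = 100 * sum(s > cutoff) / length(s))
  })
  out <- do.call(rbind, res)
  out <- cbind(band = rownames(out), out)
  rownames(out) <- NULL
  out
}
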