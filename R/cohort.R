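# Inclusion rules, per-day observation expansion, class balancing, and
# grouped cross-validation splits. Every complete day of a user is one
# labeled observation; a user with 10 complete days contributes 10
# observations carrying that user's single baseline PHQ-9 label.

# run expr with a locally seeded RNG, leaving the caller's stream untouched
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Expand feature days into labeled observations for a task
#'
#' Keeps complete days of adult users and attaches the task's label from
#' each user's baseline PHQ-9 record:
#' * `binary` - severity bands `none` vs `severe` (the deployed MHSS task);
#' * `three_class` - bands `none`, `moderate`, `severe`;
#' * `questions` - affective-subscale classes from [questionsClass()]
#'   (`none` vs `depression_symptoms`);
#' * `gyro_binary` - as `binary`, additionally requiring non-missing
#'   gyroscope features on the day.
#'
#' @param dpe a [DigitalPhenotypeExperiment] from [featurize()].
#' @param phq9 scored records from [readPhq9()].
#' @param task one of `"binary"`, `"three_class"`, `"questions"`,
#'   `"gyro_binary"`.
#' @param users optional user table from [readUsers()]; when it carries an
#'   `age_bracket` column, users in an under-18 bracket are excluded.
#' @return the experiment subset to the task's observations, with a `label`
#'   factor in `colData`.
#' @export
buildObservations <- function(dpe, phq9,
                              task = c("binary", "three_class", "questions",
                                       "gyro_binary"),
                              users = NULL) {
  task <- match.arg(task)
  cd <- colData(dpe)
  keep <- cd$complete
  if (!is.null(users) && "age_bracket" %in% names(users)) {
    minors <- users$user_id[grepl("^\\s*<\\s*18|under", users$age_bracket,
                                  ignore.case = TRUE)]
    keep <- keep & !(cd$user_id %in% minors)
  }
  lab <- if (task == "questions") {
    cls <- stats::setNames(questionsClass(phq9), phq9$user_id)
    unname(cls[as.character(cd$user_id)])
  } else {
    bnd <- stats::setNames(as.character(phq9$band), phq9$user_id)
    unname(bnd[as.character(cd$user_id)])
  }
  wanted <- switch(task,
    binary = c("none", "severe"),
    gyro_binary = c("none", "severe"),
    three_class = c("none", "moderate", "severe"),
    questions = c("none", "depression_symptoms"))
  keep <- keep & !is.na(lab) & lab %in% wanted
  if (task == "gyro_binary") {
    g <- assay(dpe, "features")[c("gyro_mean_activity",
                                  "gyro_avg_gap_activity",
                                  "gyro_total_activity"), , drop = FALSE]
    keep <- keep & colSums(is.na(g)) == 0L
  }
  obs <- dpe[, keep]
  colData(obs)$label <- factor(lab[keep], levels = wanted)
  counts <- table(colData(obs)$label)
  if (any(counts == 0L))
    stop("no observations for class(es): ",
         paste(names(counts)[counts == 0L], collapse = ", "))
  obs
}

#' Balance class sizes by resampling observations
#'
#' Default mode undersamples: every larger class is randomly subsampled
#' without replacement down to the smallest class's size, so class counts
#' come out exactly equal. `mode = "over"` instead oversamples the smaller
#' classes with replacement up to the largest. Both are reproducible under
#' a fixed `seed`.
#'
#' @param obs labeled observations from [buildObservations()].
#' @param seed integer RNG seed.
#' @param mode `"under"` (default) or `"over"`.
#' @return the balanced experiment.
#' @export
balanceClasses <- function(obs, seed = 1L, mode = c("under", "over")) {
  mode <- match.arg(mode)
  lab <- colData(obs)$label
  if (is.null(lab)) stop("observations carry no label; run buildObservations")
  counts <- table(lab)
  if (length(counts) < 2L) stop("need at least 2 classes to balance")
  target <- if (mode == "under") min(counts) else max(counts)
  idx <- .withSeed(seed, {
    unlist(lapply(levels(lab), function(l) {
      i <- which(lab == l)
      if (length(i) == target) i
      else if (length(i) > target) sample(i, target)
      else c(i, sample(i, target - length(i), replace = TRUE))
    }), use.names = FALSE)
  })
  obs[, sort(idx)]
}

#' Build a cross-validation split plan
#'
#' Default is 15-fold with folds grouped by user, so no user's days appear
#' in both a training and a test fold. Ungrouped mode assigns folds to
#' observation-days directly (stratified by label when present).
#'
#' @param obs labeled observations.
#' @param nFolds number of folds (default 15).
#' @param grouped assign folds per user rather than per day.
#' @param seed integer RNG seed.
#' @return a [SplitPlan].
#' @export
makeSplitPlan <- function(obs, nFolds = 15L, grouped = TRUE, seed = 1L) {
  nFolds <- as.integer(nFolds)
  cd <- colData(obs)
  fold <- .withSeed(seed, {
    if (grouped) {
      # stratify users by label so every fold sees every class
      uLab <- tapply(as.character(cd$label), cd$user_id, `[`, 1L)
      users <- names(uLab)
      uFold <- stats::setNames(integer(length(users)), users)
      for (l in unique(uLab)) {
        u <- sample(users[uLab == l])
        uFold[u] <- rep_len(sample(nFolds), length(u))
      }
      unname(uFold[as.character(cd$user_id)])
    } else {
      f <- integer(nrow(cd))
      for (l in unique(as.character(cd$label))) {
        i <- sample(which(cd$label == l))
        f[i] <- rep_len(sample(nFolds), length(i))
      }
      f
    }
  })
  new("SplitPlan", fold = as.integer(fold), nFolds = nFolds,
      grouped = grouped, seed = as.integer(seed))
}
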