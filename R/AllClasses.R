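#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' DigitalPhenotypeExperiment: daily behavioral biomarkers as a matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one column
#' per user-day and one row per daily digital biomarker. The single assay
#' `"features"` contains the 37 nonsensor features (session statistics,
#' per-app-category times/opens/long-session counts) and the 3 gyroscope
#' activity features; gyroscope rows are `NA` on days without sensor samples.
#' `colData` carries `user_id`, `local_date` and the `complete` flag for each
#' day, plus any label columns added by [buildObservations()].
#'
#' @slot kSd numeric(1), the SD multiplier used for the long-session
#'   ("upper") counts when the object was built.
#'
#' @seealso [featurize()], [featureLayout()], [buildObservations()]
#' @export
setClass("DigitalPhenotypeExperiment",
  contains = "SummarizedExperiment",
  slots = c(kSd = "numeric"),
  prototype = prototype(kSd = 1)
)

setValidity("DigitalPhenotypeExperiment", function(object) {
  msg <- NULL
  if (!"features" %in% assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  need <- c("user_id", "local_date", "complete")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ", paste(miss, collapse = ", ")))
  if ("features" %in% assayNames(object)) {
    a <- assay(object, "features")
    if (!is.numeric(a)) msg <- c(msg, "assay 'features' must be numeric")
    if (any(a < 0, na.rm = TRUE))
      msg <- c(msg, "daily features must be nonnegative")
  }
  if (length(object@kSd) != 1L || object@kSd < 0)
    msg <- c(msg, "kSd must be a single nonnegative number")
  if (is.null(msg)) TRUE else msg
})

#' SplitPlan: reproducible cross-validation fold assignments
#'
#' Fold labels for every observation (user-day) of a
#' [DigitalPhenotypeExperiment], optionally grouped so that no user's days
#' land in more than one fold (preventing within-user leakage between train
#' and test).
#'
#' @slot fold integer fold id per observation, in `1:nFolds`.
#' @slot nFolds integer(1) number of folds.
#' @slot grouped logical(1), `TRUE` when folds were assigned per user.
#' @slot seed integer(1) RNG seed the assignment was drawn with.
#'
#' @seealso [makeSplitPlan()]
#' @export
setClass("SplitPlan",
  slots = c(fold = "integer", nFolds = "integer", grouped = "logical",
            seed = "integer")
)

setValidity("SplitPlan", function(object) {
  msg <- NULL
  if (length(object@nFolds) != 1L || object@nFolds < 2L)
    msg <- c(msg, "nFolds must be a single integer >= 2")
  if (length(object@fold) &&
      (min(object@fold) < 1L || max(object@fold) > object@nFolds))
    msg <- c(msg, "fold ids must lie in 1:nFolds")
  if (is.null(msg)) TRUE else msg
})

#' ModelReport: cross-validated classifier performance
#'
#' Returned by [trainAndEvaluate()]. Holds per-class precision/recall/F1 and
#' overall accuracy (all percentages, aggregated as mean over folds and
#' bootstrap repeats), the Gini (mean decrease in impurity) feature
#' importance ranking where the algorithm provides one, and the final model
#' refit on all observations, which [mhssScore()] uses for scoring.
#'
#' @slot task character(1), one of `"binary"`, `"three_class"`,
#'   `"questions"`, `"gyro_binary"`.
#' @slot algorithm character(1), `"random_forest"`, `"gradient_boosting"` or
#'   `"svm_rbf"`.
#' @slot accuracy numeric(1) mean cross-validated accuracy in percent.
#' @slot accuracySd numeric(1) SD of fold accuracies.
#' @slot perClass data.frame with columns class, precision, recall, f1 (%).
#' @slot importance named numeric, normalized (sums to 1) impurity
#'   importances sorted decreasing; length 0 when unavailable.
#' @slot positiveClass character(1) label treated as the depression class.
#' @slot model ANY, the final fitted model.
#' @slot featureNames character, feature order the model expects.
#' @slot foldMetrics data.frame of per-fold accuracies.
#'
#' @export
setClass("ModelReport",
  slots = c(task = "character", algorithm = "character",
            accuracy = "numeric", accuracySd = "numeric",
            perClass = "data.frame", importance = "numeric",
            positiveClass = "character", model = "ANY",
            featureNames = "character", foldMetrics = "data.frame")
)

setValidity("ModelReport", function(object) {
  msg <- NULL
  ok01 <- function(x) all(is.finite(x) & x >= 0 & x <= 100)
  if (!ok01(object@accuracy)) msg <- c(msg, "accuracy must be in [0,100]")
  pc <- object@perClass
  if (nrow(pc)) {
    m <- as.matrix(pc[, intersect(c("precision", "recall", "f1"), names(pc))])
    if (any(m[is.finite(m)] < 0 | m[is.finite(m)] > 100))
      msg <- c(msg, "per-class metrics must be in [0,100]")
  }
  if (length(object@importance)) {
    if (any(object@importance < 0))
      msg <- c(msg, "importances must be nonnegative")
    if (is.unsorted(rev(object@importance)))
      msg <- c(msg, "importances must be sorted decreasing")
  }
  if (is.null(msg)) TRUE else msg
})

#' MhssSeries: one user's daily Mental Health Similarity Scores
#'
#' Ordered (date, score) pairs for a single user. The MHSS is 100 times the
#' classifier's predicted probability that the day's digital behavior
#' resembles that of users screening positive for depression, so every score
#' lies in [0, 100].
#'
#' @slot userId character(1).
#' @slot dates Date vector, strictly increasing.
#' @slot scores numeric vector of MHSS values in [0, 100], parallel to
#'   `dates`.
#'
#' @seealso [mhssSeries()], [majorityVerdict()]
#' @export
setClass("MhssSeries",
  slots = c(userId = "character", dates = "Date", scores = "numeric")
)

setValidity("MhssSeries", function(object) {
  msg <- NULL
  if (length(object@userId) != 1L) msg <- c(msg, "userId must be length 1")
  if (length(object@dates) != length(object@scores))
    msg <- c(msg, "dates and scores must have equal length")
  if (length(object@dates) > 1L && is.unsorted(object@dates, strictly = TRUE))
    msg <- c(msg, "dates must be strictly increasing")
  if (any(!is.finite(object@scores)) ||
      any(object@scores < 0 | object@scores > 100))
    msg <- c(msg, "scores must lie in [0, 100]")
  if (is.null(msg)) TRUE else msg
})
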