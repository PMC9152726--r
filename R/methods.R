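#' @describeIn DigitalPhenotypeExperiment-class the features-by-day matrix.
#' @export
setMethod("featureMatrix", "DigitalPhenotypeExperiment",
  function(x) assay(x, "features"))

#' @describeIn DigitalPhenotypeExperiment-class per-day metadata
#'   (`user_id`, `local_date`, `complete`, labels) as a data.frame.
#' @export
setMethod("dayInfo", "DigitalPhenotypeExperiment",
  function(x) as.data.frame(colData(x)))

setMethod("show", "DigitalPhenotypeExperiment", function(object) {
  cd <- colData(object)
  cat("DigitalPhenotypeExperiment:", nrow(object), "features x",
      ncol(object), "user-days\n")
  if (ncol(object)) {
    cat("  users:", length(unique(cd$user_id)),
        " complete days:", sum(cd$complete), "\n")
    if ("label" %in% colnames(cd))
      cat("  labels:", paste(sprintf("%s=%d", names(table(cd$label)),
                                     as.integer(table(cd$label))),
                             collapse = " "), "\n")
  }
  cat("  kSd (long-session threshold):", object@kSd, "\n")
  invisible(NULL)
})

#' @describeIn ModelReport-class mean cross-validated accuracy (percent).
#' @export
setMethod("accuracy", "ModelReport", function(x) x@accuracy)

#' @describeIn ModelReport-class normalized Gini importances, decreasing.
#' @export
setMethod("importances", "ModelReport", function(x) x@importance)

#' @describeIn ModelReport-class per-class precision/recall/F1 (percent).
#' @export
setMethod("perClassMetrics", "ModelReport", function(x) x@perClass)

setMethod("show", "ModelReport", function(object) {
  cat(sprintf("ModelReport: task=%s algorithm=%s\n",
              object@task, object@algorithm))
  cat(sprintf("  accuracy: %.1f%% (SD %.1f over %d folds)\n",
              object@accuracy, object@accuracySd, nrow(object@foldMetrics)))
  pc <- object@perClass
  for (i in seq_len(nrow(pc)))
    cat(sprintf("  %-18s precision %5.1f  recall %5.1f  F1 %5.1f\n",
                pc$class[i], pc$precision[i], pc$recall[i], pc$f1[i]))
  if (length(object@importance))
    cat("  top features:",
        paste(utils::head(names(object@importance), 5), collapse = ", "),
        "\n")
  invisible(NULL)
})

#' Construct an MhssSeries
#'
#' @param userId user identifier (length-1 character).
#' @param dates Date vector of scored days; will be sorted.
#' @param scores MHSS values in [0, 100], parallel to `dates`.
#' @return an [MhssSeries] object.
#' @export
MhssSeries <- function(userId, dates, scores) {
  o <- order(dates)
  new("MhssSeries", userId = as.character(userId),
      dates = as.Date(dates)[o], scores = as.numeric(scores)[o])
}

#' @describeIn MhssSeries-class the MHSS values, ordered by date.
#' @export
setMethod("scores", "MhssSeries", function(x) x@scores)

setMethod("length", "MhssSeries", function(x) length(x@scores))

setMethod("show", "MhssSeries", function(object) {
  cat(sprintf("MhssSeries for user %s: %d day(s)", object@userId,
              length(object@scores)))
  if (length(object@scores))
    cat(sprintf(", %s to %s, mean MHSS %.1f",
                min(object@dates), max(object@dates), mean(object@scores)))
  cat("\n")
  invisible(NULL)
})

#' @rdname majorityVerdict
#' @export
setMethod("majorityVerdict", "MhssSeries",
  function(series, window = c("overall", "weekly"), cutoff = 50) {
    window <- match.arg(window)
    if (!length(series@scores)) stop("cannot take a verdict on an empty series")
    if (window == "overall")
      return(.verdict(series@scores, cutoff))
    wk <- as.integer(series@dates - series@dates[1L]) %/% 7L
    starts <- series@dates[1L] + 7L * sort(unique(wk))
    v <- vapply(sort(unique(wk)),
                function(w) .verdict(series@scores[wk == w], cutoff), "")
    data.frame(week_start = starts,
               n_days = as.integer(table(wk)),
               verdict = v)
  })

# strict-majority rule; exactly balanced or cutoff-valued days give a tie
.verdict <- function(s, cutoff) {
  n <- length(s)
  if (sum(s > cutoff) > n / 2) "depressed"
  else if (sum(s < cutoff) > n / 2) "not_depressed"
  else "tie"
}
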