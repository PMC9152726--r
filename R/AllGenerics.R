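#' @rdname DigitalPhenotypeExperiment-class
#' @param object,x a `DigitalPhenotypeExperiment`
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname DigitalPhenotypeExperiment-class
#' @export
setGeneric("dayInfo", function(x) standardGeneric("dayInfo"))

#' @rdname ModelReport-class
#' @param object,x a `ModelReport`
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname ModelReport-class
#' @export
setGeneric("importances", function(x) standardGeneric("importances"))

#' @rdname ModelReport-class
#' @export
setGeneric("perClassMetrics", function(x) standardGeneric("perClassMetrics"))

#' @rdname MhssSeries-class
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' Majority-of-days verdict from an MHSS series
#'
#' Applies the majority-of-days rule: a user is called `"depressed"` when
#' strictly more than half of the scored days have MHSS above 50, and
#' `"not_depressed"` when strictly more than half are below 50; anything else
#' (including scores exactly at 50 tipping the balance) is a `"tie"`. With
#' `window = "weekly"` the rule is applied separately to each consecutive
#' 7-day window counted from the first scored day.
#'
#' @param series an [MhssSeries].
#' @param window `"overall"` (one verdict) or `"weekly"` (a data.frame with
#'   one verdict per 7-day window).
#' @param cutoff score threshold separating high from low days; 50 unless
#'   you have a reason to move it.
#' @return For `"overall"`, a character scalar; for `"weekly"`, a data.frame
#'   with columns `week_start`, `n_days`, `verdict`.
#' @examples
#' s <- MhssSeries("u1", as.Date("2021-11-01") + 0:2, c(60, 70, 40))
#' majorityVerdict(s)   # "depressed"
#' @export
setGeneric("majorityVerdict",
  function(series, window = c("overall", "weekly"), cutoff = 50)
    standardGeneric("majorityVerdict"))
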