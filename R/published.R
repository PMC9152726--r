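# Reference cohort distributions shipped with the package. These are the
# marginal distributions of the 558-participant reference cohort the
# simulator's defaults are anchored to; they let the simulator reproduce a
# realistic PHQ-9 score histogram and demographic mix exactly, and give the
# summary-table functions a worked example with known arithmetic.

#' Reference PHQ-9 score histogram
#'
#' Participant counts per exact PHQ-9 total (0-27) for the 558-respondent
#' reference cohort. Band subtotals are 63 (none), 124 (mild), 162
#' (moderate), 134 (moderately severe) and 75 (severe).
#'
#' @return data.frame with columns `total` (0-27) and `n`.
#' @export
referencePhq9Histogram <- function() {
  data.frame(
    total = 0:27,
    n = c(20L, 6L, 12L, 7L, 18L,          # none: 63
          13L, 33L, 23L, 37L, 18L,        # mild: 124
          23L, 28L, 29L, 43L, 39L,        # moderate: 162
          29L, 31L, 26L, 31L, 17L,        # moderately severe: 134
          16L, 16L, 13L, 6L, 10L, 5L, 1L, 8L))  # severe: 75
}

#' Reference cohort demographics
#'
#' Marginal counts for the 558-participant reference cohort: age brackets,
#' gender, questionnaire language, the per-band no-prior-diagnosis counts
#' (499 users in total reported no prior diagnosis of any kind), and the
#' gender split within each severity band.
#'
#' @return list of named integer vectors: `age`, `gender`, `language`,
#'   `no_diagnosis_by_band`, and a data.frame `gender_by_band`.
#' @export
referenceDemographics <- function() {
  list(
    age = c("18-25" = 474L, "26-35" = 29L, "36-55" = 42L,
            "56-64" = 10L, ">64" = 3L),
    gender = c(male = 254L, female = 286L, other = 18L),
    language = c(korean = 487L, english = 71L),
    no_diagnosis_by_band = c(none = 63L, mild = 113L, moderate = 145L,
                             moderately_severe = 119L, severe = 59L),
    gender_by_band = data.frame(
      band = c("none", "mild", "moderate", "moderately_severe", "severe"),
      male = c(41L, 69L, 73L, 48L, 24L),
      female = c(21L, 52L, 82L, 82L, 47L),
      other = c(1L, 3L, 7L, 4L, 4L))
  )
}
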