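# PHQ-9 scoring. Nine items scored 0 (not at all) to 3 (nearly every day);
# total 0-27; severity bands: none (<5), mild (5-9), moderate (10-14),
# moderately severe (15-19), severe (20-27). Items 2, 6 and 9 form the
# affective-cognitive subscale.

.PHQ_BANDS <- c("none", "mild", "moderate", "moderately_severe", "severe")

#' Severity band for a PHQ-9 total
#'
#' @param total integer total score(s) in 0-27.
#' @return factor with levels none, mild, moderate, moderately_severe,
#'   severe. The severe band starts at 20 inclusive.
#' @export
phq9Band <- function(total) {
  if (any(total < 0 | total > 27 | total != round(total)))
    stop("PHQ-9 totals must be integers in 0..27")
  cut(total, breaks = c(-1, 4, 9, 14, 19, 27), labels = .PHQ_BANDS)
}

#' Score one PHQ-9 response
#'
#' @param items integer vector of the 9 item scores, each in 0-3.
#' @param userId optional user identifier carried along.
#' @return one-row data.frame with the nine items (`q1`..`q9`), `total`,
#'   `band`, and `affective_269` (the item 2 + 6 + 9 affective-cognitive
#'   subscale, 0-9).
#' @examples
#' scorePhq9(rep(3, 9))$band   # severe
#' @export
scorePhq9 <- function(items, userId = NA_character_) {
  if (length(items) != 9L)
    stop("a PHQ-9 response has exactly 9 items")
  if (any(is.na(items)) || any(!items %in% 0:3))
    stop("each PHQ-9 item must be an integer in 0..3")
  items <- as.integer(items)
  total <- sum(items)
  out <- data.frame(user_id = userId, t(stats::setNames(items,
                                                        paste0("q", 1:9))),
                    total = total, band = phq9Band(total),
                    affective_269 = items[2L] + items[6L] + items[9L],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read and score a PHQ-9 response file
#'
#' One questionnaire per user (a single baseline time point); when a user
#' has several rows the earliest `timestamp` wins.
#'
#' @param path CSV with columns `user_id,q1..q9` and optionally
#'   `timestamp,language`, or an equivalent data.frame.
#' @return data.frame of scored records, one row per user.
#' @export
readPhq9 <- function(path) {
  d <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("user_id", paste0("q", 1:9))
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("phq9 input lacks column(s): ", paste(miss, collapse = ", "))
  if ("timestamp" %in% names(d)) d <- d[order(d$timestamp), , drop = FALSE]
  d <- d[!duplicated(d$user_id), , drop = FALSE]
  rec <- do.call(rbind, lapply(seq_len(nrow(d)), function(i)
    scorePhq9(as.integer(d[i, paste0("q", 1:9)]), d$user_id[i])))
  if ("language" %in% names(d)) rec$language <- d$language
  rec[order(rec$user_id), , drop = FALSE]
}

#' Band and score histogram of PHQ-9 records
#'
#' @param records scored records from [readPhq9()] / [scorePhq9()].
#' @return list with `by_band` (count and percent per severity band),
#'   `by_total` (count and percent per exact total 0-27), `n`, and
#'   `pct_depressed`, the percentage of respondents scoring 5 or above
#'   (any sign of depression).
#' @export
bandHistogram <- function(records) {
  if (!nrow(records)) stop("no PHQ-9 records")
  n <- nrow(records)
  bands <- factor(records$band, levels = .PHQ_BANDS)
  byBand <- data.frame(band = .PHQ_BANDS,
                       n = as.integer(table(bands)),
                       pct = round(100 * as.integer(table(bands)) / n, 1))
  tot <- factor(records$total, levels = 0:27)
  byTotal <- data.frame(total = 0:27,
                        n = as.integer(table(tot)),
                        pct = round(100 * as.integer(table(tot)) / n, 1))
  list(by_band = byBand, by_total = byTotal, n = n,
       pct_depressed = 100 * sum(records$total >= 5) / n)
}

#' Affective-subscale class for the questions model
#'
#' The questions model contrasts respondents scoring 0 on all of items 2, 6
#' and 9 (`"none"`) with respondents scoring 3 on all three
#' (`"depression_symptoms"`); everyone else is `"unassigned"` and excluded
#' from that task.
#'
#' @param record a scored record (row) with columns `q2`, `q6`, `q9`, or a
#'   data.frame of them.
#' @return character vector of class labels.
#' @export
questionsClass <- function(record) {
  q <- cbind(record$q2, record$q6, record$q9)
  ifelse(rowSums(q == 0L) == 3L, "none",
         ifelse(rowSums(q == 3L) == 3L, "depression_symptoms", "unassigned"))
}
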