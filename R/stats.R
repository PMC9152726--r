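# Cohort statistics: one-tailed Welch comparisons with Cohen's d, per-item
# PHQ-9 / MHSS correlations, and demographic summary tables.

#' Compare a daily feature between two cohorts
#'
#' Welch's unequal-variance t-test, one-tailed in the direction of the
#' observed mean difference (the unequal-variance form is the right default
#' here: cohort SDs of daily behavioral features routinely differ several
#' fold). Effect size is Cohen's d, reported as a magnitude; `pooled = TRUE`
#' (default) weights the pooled SD by sample sizes, `pooled = FALSE` uses
#' the unweighted average of the two variances.
#'
#' @param x,y numeric feature values for cohorts A and B (>= 2 each).
#' @param feature optional feature name carried into the result.
#' @param pooled weight the pooled SD by sample size.
#' @return one-row data.frame: feature, per-cohort mean/sd/n, `t`, `df`,
#'   one-tailed `p`, `cohen_d`, and `direction` (`"greater"` when cohort B's
#'   mean is higher).
#' @export
compareFeature <- function(x, y, feature = NA_character_, pooled = TRUE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each cohort needs at least 2 finite values")
  nx <- length(x); ny <- length(y)
  sx <- stats::sd(x); sy <- stats::sd(y)
  sp <- if (pooled)
    sqrt(((nx - 1) * sx^2 + (ny - 1) * sy^2) / (nx + ny - 2)) else
    sqrt((sx^2 + sy^2) / 2)
  d <- if (sp == 0) 0 else abs(mean(y) - mean(x)) / sp
  if (sx == 0 && sy == 0) {
    # degenerate: no spread anywhere; equal means carry no evidence
    p <- if (mean(x) == mean(y)) 0.5 else 0
    tt <- list(statistic = c(t = if (mean(x) == mean(y)) 0 else Inf),
               parameter = c(df = nx + ny - 2), p.value = p)
  } else {
    alt <- if (mean(y) >= mean(x)) "greater" else "less"
    tt <- stats::t.test(y, x, alternative = alt, var.equal = FALSE)
  }
  data.frame(feature = feature,
             mean_a = mean(x), sd_a = sx, n_a = nx,
             mean_b = mean(y), sd_b = sy, n_b = ny,
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, cohen_d = d,
             direction = if (mean(y) >= mean(x)) "greater" else "less",
             stringsAsFactors = FALSE)
}

#' Feature comparison table between two cohorts of observations
#'
#' Applies [compareFeature()] to every feature row, contrasting the
#' observations of two label classes (per-day observations, matching the
#' observation-expansion design).
#'
#' @param obs labeled observations from [buildObservations()].
#' @param classA,classB label values to contrast (cohort A vs B).
#' @return data.frame, one row per feature, sorted by `cohen_d` decreasing.
#' @export
compareCohorts <- function(obs, classA = "none", classB = "severe") {
  lab <- colData(obs)$label
  m <- assay(obs, "features")
  rows <- lapply(rownames(m), function(f) {
    x <- m[f, lab == classA]; y <- m[f, lab == classB]
    if (sum(is.finite(x)) < 2L || sum(is.finite(y)) < 2L) return(NULL)
    compareFeature(x, y, feature = f)
  })
  out <- do.call(rbind, rows)
  out[order(-out$cohen_d), , drop = FALSE]
}

#' Correlation between PHQ-9 items and the baseline-day MHSS
#'
#' Pearson and Spearman correlations between an item score (or the sum over
#' an item set, e.g. the affective-cognitive subscale 2+6+9) and each user's
#' MHSS on the day of baseline assessment, restricted to a band cohort when
#' `band` is given.
#'
#' @param records scored PHQ-9 records.
#' @param mhssAtBaseline named numeric, user id -> baseline-day MHSS.
#' @param items integer item indices to sum (e.g. `2` or `c(2, 6, 9)`).
#' @param band optional severity band to restrict to (e.g. `"severe"`).
#' @return one-row data.frame with `label`, `n`, `pearson_r`,
#'   `spearman_rho`; correlations are `NA` with a warning when either
#'   vector has zero variance.
#' @export
itemMhssCorrelation <- function(records, mhssAtBaseline, items,
                                band = NULL) {
  if (!is.null(band)) records <- records[records$band %in% band, , drop = FALSE]
  ids <- intersect(records$user_id, names(mhssAtBaseline))
  if (length(ids) < 3L) stop("need >= 3 paired users")
  rec <- records[match(ids, records$user_id), , drop = FALSE]
  v <- rowSums(rec[, paste0("q", items), drop = FALSE])
  s <- unname(mhssAtBaseline[ids])
  lab <- paste0("q", paste(items, collapse = "+q"))
  if (stats::sd(v) == 0 || stats::sd(s) == 0) {
    warning("zero variance; correlation undefined for ", lab)
    return(data.frame(label = lab, n = length(ids), pearson_r = NA_real_,
                      spearman_rho = NA_real_))
  }
  data.frame(label = lab, n = length(ids),
             pearson_r = stats::cor(v, s, method = "pearson"),
             spearman_rho = stats::cor(v, s, method = "spearman"))
}

#' Demographic and severity summary tables
#'
#' Count/percentage breakdowns of a cohort: by age bracket, gender and
#' language; by severity band; gender within band; and severity band within
#' the users reporting no prior diagnosis (with the count scoring at least
#' moderate, i.e. total >= 10).
#'
#' @param users user table from [readUsers()].
#' @param phq9 scored records from [readPhq9()].
#' @return list of data.frames: `age`, `gender`, `language`, `band`,
#'   `gender_by_band`, `no_diagnosis`, plus scalars `n`,
#'   `n_no_diagnosis`, `n_no_diagnosis_moderate_plus`.
#' @export
cohortTables <- function(users, phq9) {
  u <- merge(users, phq9[, c("user_id", "total", "band")], by = "user_id")
  n <- nrow(u)
  cnt <- function(x) {
    tab <- table(x)
    data.frame(value = names(tab), n = as.integer(tab),
               pct = round(100 * as.integer(tab) / n, 1))
  }
  bands <- factor(u$band, levels = .PHQ_BANDS)
  out <- list(
    age = if ("age_bracket" %in% names(u)) cnt(u$age_bracket) else NULL,
    gender = if ("gender" %in% names(u)) cnt(u$gender) else NULL,
    language = if ("language" %in% names(u)) cnt(u$language) else NULL,
    band = data.frame(band = .PHQ_BANDS, n = as.integer(table(bands)),
                      pct = round(100 * as.integer(table(bands)) / n, 1)),
    n = n)
  if ("gender" %in% names(u))
    out$gender_by_band <- as.data.frame(table(band = bands,
                                              gender = u$gender))
  if ("prior_diagnosis" %in% names(u)) {
    nd <- u[u$prior_diagnosis %in% c("none", "no", FALSE, "FALSE"), ,
            drop = FALSE]
    ndBands <- factor(nd$band, levels = .PHQ_BANDS)
    out$no_diagnosis <- data.frame(
      band = .PHQ_BANDS, n = as.integer(table(ndBands)),
      pct = round(100 * as.integer(table(ndBands)) / nrow(nd), 1))
    out$n_no_diagnosis <- nrow(nd)
    out$n_no_diagnosis_moderate_plus <- sum(nd$total >= 10)
  }
  out
}
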