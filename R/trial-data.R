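#' Trial data container
#'
#' A `pp_trial` bundles one baseline record per participant with a long table
#' of weekly follow-up records. It is the common input to adherence
#' derivation, descriptive tables, and the effect estimators.
#'
#' @param baseline data frame with one row per woman: `id`, `arm`
#'   (`"aspirin"`/`"placebo"`), `outcome_hcg` (0/1), `pregnancy_week`
#'   (integer week of hCG detection, `NA` if none), and the baseline
#'   covariates `age`, `white`, `hs_education`, `married`, `employed`,
#'   `income_ge_40k`, `exercise` (`"low"`/`"moderate"`/`"high"`),
#'   `prior_losses` (1 or 2), `prior_live_births` (0-3),
#'   `alcohol_past_year`, `smoked_past_year`, `months_trying`, `bmi`,
#'   `hscrp`.
#' @param weekly data frame with one row per woman-week: `id`, `week`
#'   (1-based), `pill_days`, `bleeding_days`, `nausea_days`, all day counts
#'   in 0-7. Weeks run up to pregnancy (inclusive) or the follow-up cap.
#'
#' @return An object of class `pp_trial`.
#' @export
pp_trial <- function(baseline, weekly) {
  req_b <- c("id", "arm", "outcome_hcg", "pregnancy_week", baseline_covariate_names())
  miss <- setdiff(req_b, names(baseline))
  if (length(miss)) stopf("baseline table lacks columns: %s", paste(miss, collapse = ", "))
  req_w <- c("id", "week", "pill_days", "bleeding_days", "nausea_days")
  miss <- setdiff(req_w, names(weekly))
  if (length(miss)) stopf("weekly table lacks columns: %s", paste(miss, collapse = ", "))
  if (!all(baseline$arm %in% c("aspirin", "placebo")))
    stopf("arm must be 'aspirin' or 'placebo'")
  for (col in c("pill_days", "bleeding_days", "nausea_days")) {
    v <- weekly[[col]]
    if (any(v < 0 | v > 7 | v != round(v))) stopf("%s must be integer day counts in 0-7", col)
  }
  if (!all(weekly$id %in% baseline$id)) stopf("weekly records reference unknown ids")
  if (!all(baseline$id %in% weekly$id))
    stopf("no weekly records for id(s): %s",
          paste(utils::head(setdiff(baseline$id, weekly$id), 5), collapse = ", "))
  bad <- !is.na(baseline$pregnancy_week) & baseline$outcome_hcg != 1L
  bad <- bad | (is.na(baseline$pregnancy_week) & baseline$outcome_hcg == 1L)
  if (any(bad)) stopf("outcome_hcg must be 1 exactly when pregnancy_week is set (ids: %s)",
                      paste(utils::head(baseline$id[bad], 5), collapse = ", "))
  structure(list(baseline = as.data.frame(baseline), weekly = as.data.frame(weekly)),
            class = "pp_trial")
}

#' @export
print.pp_trial <- function(x, ...) {
  n <- nrow(x$baseline)
  cat(sprintf("<pp_trial> %d participants (%d aspirin / %d placebo), %d person-weeks, %d pregnancies\n",
              n, sum(x$baseline$arm == "aspirin"), sum(x$baseline$arm == "placebo"),
              nrow(x$weekly), sum(x$baseline$outcome_hcg)))
  invisible(x)
}

#' Baseline covariate names in canonical order
#' @return Character vector of the raw baseline covariate columns.
#' @export
baseline_covariate_names <- function() {
  c("age", "white", "hs_education", "married", "employed", "income_ge_40k",
    "exercise", "prior_losses", "prior_live_births", "alcohol_past_year",
    "smoked_past_year", "months_trying", "bmi", "hscrp")
}

#' Encoded covariate column order
#'
#' Fixed design-matrix encoding used by every model in the package:
#' categorical covariates are expanded to indicators (exercise: moderate and
#' high, low as reference; prior live births: 1, 2, 3 with 0 as reference;
#' prior losses: indicator of 2 vs 1), continuous covariates enter as-is.
#'
#' @return Character vector of encoded column names.
#' @export
encoded_covariate_names <- function() {
  c("age", "white", "hs_education", "married", "employed", "income_ge_40k",
    "exercise_moderate", "exercise_high", "prior_losses_2",
    "prior_live_births_1", "prior_live_births_2", "prior_live_births_3",
    "alcohol_past_year", "smoked_past_year", "months_trying", "bmi", "hscrp")
}

#' Encode baseline covariates as a numeric matrix
#'
#' @param baseline baseline data frame (see [pp_trial()]).
#' @return Numeric matrix, one row per woman, columns as
#'   [encoded_covariate_names()].
#' @export
covariate_matrix <- function(baseline) {
  W <- cbind(
    age = baseline$age,
    white = baseline$white,
    hs_education = baseline$hs_education,
    married = baseline$married,
    employed = baseline$employed,
    income_ge_40k = baseline$income_ge_40k,
    exercise_moderate = as.numeric(baseline$exercise == "moderate"),
    exercise_high = as.numeric(baseline$exercise == "high"),
    prior_losses_2 = as.numeric(baseline$prior_losses == 2),
    prior_live_births_1 = as.numeric(baseline$prior_live_births == 1),
    prior_live_births_2 = as.numeric(baseline$prior_live_births == 2),
    prior_live_births_3 = as.numeric(baseline$prior_live_births >= 3),
    alcohol_past_year = baseline$alcohol_past_year,
    smoked_past_year = baseline$smoked_past_year,
    months_trying = baseline$months_trying,
    bmi = baseline$bmi,
    hscrp = baseline$hscrp
  )
  storage.mode(W) <- "double"
  W
}

#' Extract a single participant's history
#'
#' @param trial a [pp_trial()].
#' @param id participant id.
#' @return List with `id`, `arm`, `baseline` (one-row data frame),
#'   `weeks` (data frame of weekly records ordered by week),
#'   `outcome_hcg`, `pregnancy_week` (`NA` if none).
#' @export
participant_history <- function(trial, id) {
  i <- match(id, trial$baseline$id)
  if (is.na(i)) stopf("unknown participant id: %s", id)
  wk <- trial$weekly[trial$weekly$id == id, , drop = FALSE]
  wk <- wk[order(wk$week), , drop = FALSE]
  list(id = id,
       arm = trial$baseline$arm[i],
       baseline = trial$baseline[i, , drop = FALSE],
       weeks = wk,
       outcome_hcg = trial$baseline$outcome_hcg[i],
       pregnancy_week = trial$baseline$pregnancy_week[i])
}

#' Write / read a trial as a pair of CSV files
#'
#' The on-disk format is two plain CSVs: `<stem>_baseline.csv` (one row per
#' woman) and `<stem>_weekly.csv` (one row per woman-week), with the column
#' dictionary of [pp_trial()]. `read_trial_csv()` round-trips what
#' `write_trial_csv()` wrote.
#'
#' @param trial a [pp_trial()].
#' @param stem path stem; the two files get `_baseline.csv` / `_weekly.csv`
#'   suffixes.
#' @return `write_trial_csv()` returns the two paths invisibly;
#'   `read_trial_csv()` returns a [pp_trial()].
#' @export
write_trial_csv <- function(trial, stem) {
  pb <- paste0(stem, "_baseline.csv")
  pw <- paste0(stem, "_weekly.csv")
  utils::write.csv(trial$baseline, pb, row.names = FALSE)
  utils::write.csv(trial$weekly, pw, row.names = FALSE)
  invisible(c(baseline = pb, weekly = pw))
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(stem) {
  pb <- paste0(stem, "_baseline.csv")
  pw <- paste0(stem, "_weekly.csv")
  baseline <- utils::read.csv(pb, stringsAsFactors = FALSE)
  weekly <- utils::read.csv(pw, stringsAsFactors = FALSE)
  baseline$pregnancy_week <- as.integer(baseline$pregnancy_week)
  pp_trial(baseline, weekly)
}
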