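#' Adherence protocol definition
#'
#' A protocol `(d, f)` classifies a woman as adherent when she took her
#' assigned pills on at least `d` of 7 days in at least a fraction `f` of
#' her person-weeks of follow-up before pregnancy (or all follow-up if no
#' pregnancy). The primary analysis uses `protocol(5, 0.8)`; the sensitivity
#' grid crosses d in {4, 5, 6} with f in {0.60, 0.70, 0.80}.
#'
#' @param d minimum pill-days per week, integer in 1-7.
#' @param f minimum fraction of person-weeks, in (0, 1].
#' @return An object of class `pp_protocol`.
#' @export
protocol <- function(d = 5L, f = 0.8) {
  if (!is.numeric(d) || length(d) != 1L || d != round(d) || d < 1 || d > 7)
    stopf("`d` must be an integer in 1-7")
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1)
    stopf("`f` must be a fraction in (0, 1]")
  structure(list(d = as.integer(d), f = as.numeric(f)), class = "pp_protocol")
}

#' @export
print.pp_protocol <- function(x, ...) {
  cat(sprintf("<protocol> >= %d of 7 pill-days per week for >= %d%% of person-weeks\n",
              x$d, round(100 * x$f)))
  invisible(x)
}

#' The 3 x 3 sensitivity grid of protocols
#' @return List of 9 [protocol()] objects, d in {4,5,6} crossed with
#'   f in {0.6, 0.7, 0.8} (d varying fastest).
#' @export
protocol_grid <- function() {
  out <- list()
  for (f in c(0.6, 0.7, 0.8)) for (d in c(4L, 5L, 6L))
    out[[length(out) + 1L]] <- protocol(d, f)
  out
}

#' Weekly adherence indicator
#'
#' A week counts as adherent when the assigned pills were taken on at least
#' `d` of its 7 days (the boundary is inclusive).
#'
#' @param pill_days integer vector of pill-days (0-7), or a weekly record
#'   data frame with a `pill_days` column.
#' @param d minimum pill-days per week (1-7).
#' @return Integer 0/1 vector.
#' @export
weekly_adherent <- function(pill_days, d = 5L) {
  if (is.data.frame(pill_days)) pill_days <- pill_days$pill_days
  if (!is.numeric(d) || length(d) != 1L || d != round(d) || d < 1 || d > 7)
    stopf("`d` must be an integer in 1-7")
  if (any(pill_days < 0 | pill_days > 7)) stopf("pill_days must be in 0-7")
  as.integer(pill_days >= d)
}

# evaluation window: weeks up to and including pregnancy_week, else all weeks
follow_up_window <- function(history) {
  wk <- history$weeks
  if (!is.na(history$pregnancy_week)) wk <- wk[wk$week <= history$pregnancy_week, , drop = FALSE]
  if (nrow(wk) == 0L) stopf("participant %s has an empty follow-up window", history$id)
  wk
}

#' Overall (time-fixed) adherence indicator
#'
#' Dichotomizes a woman's longitudinal pill-taking into a single adherence
#' status: 1 when the fraction of adherent weeks within her follow-up window
#' (weeks up to pregnancy for women with an hCG-detected pregnancy, all
#' weeks otherwise) is at least the protocol's `f`.
#'
#' @param history a participant history (see [participant_history()]).
#' @param p a [protocol()].
#' @return Integer 0/1.
#' @export
overall_adherent <- function(history, p = protocol()) {
  wk <- follow_up_window(history)
  as.integer(mean(weekly_adherent(wk$pill_days, p$d)) >= p$f)
}

#' Postrandomization side-effect flags
#'
#' `bleeding_flag()` is 1 when at least 50% of follow-up weeks had unusual
#' bleeding on >= 1 of 7 days; `nausea_flag()` uses the same rule with a 20%
#' person-week threshold. Both are evaluated over the same pre-pregnancy
#' window as adherence.
#'
#' @param history a participant history.
#' @return Integer 0/1.
#' @export
bleeding_flag <- function(history) {
  wk <- follow_up_window(history)
  as.integer(mean(wk$bleeding_days >= 1) >= 0.50)
}

#' @rdname bleeding_flag
#' @export
nausea_flag <- function(history) {
  wk <- follow_up_window(history)
  as.integer(mean(wk$nausea_days >= 1) >= 0.20)
}

#' Build the analytic dataset for a protocol
#'
#' Flattens a trial into one row per woman: randomized arm as exposure `A`
#' (1 = aspirin), time-fixed adherence `C` under protocol `p`, outcome `Y`
#' (hCG-detected pregnancy), the encoded baseline covariates (see
#' [encoded_covariate_names()]), and the dichotomized postrandomization
#' confounders `bleeding_flag` and `nausea_flag`.
#'
#' @param trial a [pp_trial()].
#' @param p a [protocol()].
#' @return Data frame with columns `id`, `A`, `C`, `Y`, the encoded
#'   covariates, `bleeding_flag`, `nausea_flag`. The attribute
#'   `"covariates"` records the covariate column names.
#' @export
build_analytic <- function(trial, p = protocol()) {
  if (!inherits(trial, "pp_trial")) stopf("`trial` must be a pp_trial")
  if (nrow(trial$baseline) == 0L) stopf("trial has no participants")
  b <- trial$baseline
  wk <- trial$weekly
  preg <- b$pregnancy_week[match(wk$id, b$id)]
  wk <- wk[is.na(preg) | wk$week <= preg, , drop = FALSE]
  if (!all(b$id %in% wk$id)) {
    bad <- setdiff(b$id, wk$id)
    stopf("empty follow-up window for id(s): %s", paste(utils::head(bad, 5), collapse = ", "))
  }
  grp <- factor(wk$id, levels = b$id)
  sums <- rowsum(cbind(one = rep(1, nrow(wk)),
                       adh = as.numeric(wk$pill_days >= p$d),
                       bleed = as.numeric(wk$bleeding_days >= 1),
                       naus = as.numeric(wk$nausea_days >= 1)),
                 group = grp, reorder = FALSE)
  agg <- data.frame(adh = sums[, "adh"] / sums[, "one"],
                    bleed = sums[, "bleed"] / sums[, "one"],
                    naus = sums[, "naus"] / sums[, "one"])
  W <- covariate_matrix(b)
  out <- data.frame(id = b$id,
                    A = as.integer(b$arm == "aspirin"),
                    C = as.integer(agg$adh >= p$f),
                    Y = as.integer(b$outcome_hcg),
                    W,
                    bleeding_flag = as.integer(agg$bleed >= 0.50),
                    nausea_flag = as.integer(agg$naus >= 0.20))
  attr(out, "covariates") <- encoded_covariate_names()
  attr(out, "protocol") <- p
  out
}
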