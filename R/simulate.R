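#' Parameters of the synthetic trial generator
#'
#' Defines a data-generating process emulating a preconception aspirin
#' trial: ~1227 women, 1:1 randomization, baseline covariates matched to
#' published margins, weekly pill-taking that declines over follow-up and is
#' depressed by prior-week bleeding, arm-dependent bleeding side effects,
#' and a weekly pregnancy hazard in which treatment acts only through actual
#' pill ingestion (taking >= `ingestion_threshold` pills in a week while on
#' aspirin). Follow-up ends at pregnancy or `max_weeks`.
#'
#' All linear predictors are on the logit scale. Continuous covariates enter
#' the weekly models through fixed standardizations (age centered at its
#' generating mean; log-BMI, log-hsCRP and log-months-trying centered at
#' their generating means), so the defaults stay interpretable when a single
#' parameter is changed.
#'
#' @param n_participants number of women.
#' @param p_assign probability of assignment to the aspirin arm.
#' @param max_weeks follow-up cap in weeks.
#' @param covariate_prevalences named probabilities for the binary baseline
#'   covariates.
#' @param exercise_probs,prior_losses_probs,prior_live_births_probs
#'   category probabilities (must each sum to 1).
#' @param age_mean,age_sd years; age is truncated to \[18, 40\].
#' @param months_trying_meanlog,months_trying_sdlog,bmi_meanlog,bmi_sdlog,hscrp_meanlog,hscrp_sdlog
#'   log-normal parameters for the continuous covariates.
#' @param adherence_coefs named coefficients of the weekly pill-taking
#'   model: `intercept`, per-covariate terms, `week` (per elapsed week),
#'   `prev_bleeding` (indicator of any bleeding in the prior week), and
#'   `noise_sd`, the scale of a woman-level normal disturbance driven by an
#'   independent uniform (heterogeneity that is independent of the outcome
#'   given covariates and ingestion).
#' @param side_effect_coefs named coefficients of the weekly bleeding and
#'   nausea day-count models; `bleed_arm` is the aspirin effect on bleeding.
#' @param outcome_coefs named coefficients of the weekly pregnancy hazard;
#'   `treat` multiplies the ingestion indicator (pill-days >=
#'   `ingestion_threshold` while assigned aspirin).
#' @param ingestion_threshold pill-days per week needed for a biological
#'   aspirin dose.
#' @param adherence_frailty_sd unmeasured-confounding switch, off (0) by
#'   default: when positive, a woman-level frailty of this SD enters both
#'   the pill-taking model and (scaled by `frailty_outcome_coef`) the
#'   pregnancy hazard, breaking identification by baseline adjustment.
#' @param frailty_outcome_coef hazard loading of the frailty.
#' @param seed integer seed used by [simulate_trial()] when no explicit
#'   seed is given.
#' @return Object of class `dgp_params` (a validated list).
#' @export
dgp_params <- function(n_participants = 1227L,
                       p_assign = 0.5,
                       max_weeks = 26L,
                       covariate_prevalences = c(white = 0.946, hs_education = 0.861,
                                                 married = 0.915, employed = 0.749,
                                                 income_ge_40k = 0.669,
                                                 alcohol_past_year = 0.333,
                                                 smoked_past_year = 0.124),
                       exercise_probs = c(low = 0.262, moderate = 0.408, high = 0.330),
                       prior_losses_probs = c("1" = 0.328, "2" = 0.672),
                       prior_live_births_probs = c("0" = 0.428, "1" = 0.353,
                                                   "2" = 0.201, "3" = 0.018),
                       age_mean = 28.74, age_sd = 4.80,
                       months_trying_meanlog = 1.10, months_trying_sdlog = 1.40,
                       bmi_meanlog = 3.203, bmi_sdlog = 0.241,
                       hscrp_meanlog = -2.16, hscrp_sdlog = 1.38,
                       adherence_coefs = c(intercept = 1.60, white = 0.40,
                                           hs_education = 0.30, married = 0.50,
                                           income_ge_40k = 0.30,
                                           smoked_past_year = -0.70,
                                           age_std = 0.15, week = -0.05,
                                           prev_bleeding = -0.45, noise_sd = 2.00),
                       side_effect_coefs = c(bleed_intercept = -3.40, bleed_arm = 0.45,
                                             bleed_hscrp_std = 0.60,
                                             nausea_intercept = -4.20,
                                             nausea_bmi_std = 0.50),
                       outcome_coefs = c(intercept = -3.15, treat = 0.24,
                                         age_std = -0.10, bmi_std = -0.12,
                                         hscrp_std = -0.10, smoked_past_year = -0.25,
                                         months_trying_std = -0.20,
                                         prior_losses_2 = -0.10),
                       ingestion_threshold = 5L,
                       adherence_frailty_sd = 0,
                       frailty_outcome_coef = 0.5,
                       seed = 20260101L) {
  p <- list(n_participants = as.integer(n_participants), p_assign = p_assign,
            max_weeks = as.integer(max_weeks),
            covariate_prevalences = covariate_prevalences,
            exercise_probs = exercise_probs,
            prior_losses_probs = prior_losses_probs,
            prior_live_births_probs = prior_live_births_probs,
            age_mean = age_mean, age_sd = age_sd,
            months_trying_meanlog = months_trying_meanlog,
            months_trying_sdlog = months_trying_sdlog,
            bmi_meanlog = bmi_meanlog, bmi_sdlog = bmi_sdlog,
            hscrp_meanlog = hscrp_meanlog, hscrp_sdlog = hscrp_sdlog,
            adherence_coefs = adherence_coefs,
            side_effect_coefs = side_effect_coefs,
            outcome_coefs = outcome_coefs,
            ingestion_threshold = as.integer(ingestion_threshold),
            adherence_frailty_sd = adherence_frailty_sd,
            frailty_outcome_coef = frailty_outcome_coef,
            seed = as.integer(seed))
  validate_dgp_params(p)
  structure(p, class = "dgp_params")
}

validate_dgp_params <- function(p) {
  if (p$n_participants < 1L) stopf("n_participants must be positive")
  assert_prob(p$p_assign, "p_assign")
  assert_prob(p$covariate_prevalences, "covariate_prevalences")
  if (p$max_weeks < 1L) stopf("max_weeks must be >= 1")
  for (nm in c("exercise_probs", "prior_losses_probs", "prior_live_births_probs")) {
    assert_prob(p[[nm]], nm)
    if (abs(sum(p[[nm]]) - 1) > 1e-8) stopf("`%s` must sum to 1", nm)
  }
  if (p$ingestion_threshold < 1L || p$ingestion_threshold > 7L)
    stopf("ingestion_threshold must be in 1-7")
  if (p$adherence_frailty_sd < 0) stopf("adherence_frailty_sd must be >= 0")
  invisible(p)
}

#' Serialize generator parameters to / from YAML
#' @param params a [dgp_params()] object.
#' @param path file path.
#' @return `read_dgp_params()` returns a validated [dgp_params()].
#' @export
write_dgp_params <- function(params, path) {
  out <- unclass(params)
  for (nm in c("covariate_prevalences", "exercise_probs", "prior_losses_probs",
               "prior_live_births_probs", "adherence_coefs", "side_effect_coefs",
               "outcome_coefs"))
    out[[nm]] <- as.list(out[[nm]])  # named map, not a bare sequence
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_dgp_params
#' @export
read_dgp_params <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("covariate_prevalences", "exercise_probs", "prior_losses_probs",
               "prior_live_births_probs", "adherence_coefs", "side_effect_coefs",
               "outcome_coefs"))
    raw[[nm]] <- unlist(raw[[nm]])
  do.call(dgp_params, raw)
}

# ---- core simulation -------------------------------------------------------

# Draw baseline covariates and every uniform the weekly processes consume.
# Returning raw uniforms (not realized draws) lets the counterfactual
# trajectories under forced aspirin / forced placebo share all randomness.
draw_population <- function(params, n) {
  cp <- params$covariate_prevalences
  baseline <- data.frame(
    id = seq_len(n),
    age = pmin(pmax(stats::rnorm(n, params$age_mean, params$age_sd), 18), 40),
    white = stats::rbinom(n, 1, cp[["white"]]),
    hs_education = stats::rbinom(n, 1, cp[["hs_education"]]),
    married = stats::rbinom(n, 1, cp[["married"]]),
    employed = stats::rbinom(n, 1, cp[["employed"]]),
    income_ge_40k = stats::rbinom(n, 1, cp[["income_ge_40k"]]),
    exercise = sample(names(params$exercise_probs), n, TRUE, params$exercise_probs),
    prior_losses = as.integer(sample(names(params$prior_losses_probs), n, TRUE,
                                     params$prior_losses_probs)),
    prior_live_births = as.integer(sample(names(params$prior_live_births_probs), n, TRUE,
                                          params$prior_live_births_probs)),
    alcohol_past_year = stats::rbinom(n, 1, cp[["alcohol_past_year"]]),
    smoked_past_year = stats::rbinom(n, 1, cp[["smoked_past_year"]]),
    months_trying = stats::rlnorm(n, params$months_trying_meanlog, params$months_trying_sdlog),
    bmi = stats::rlnorm(n, params$bmi_meanlog, params$bmi_sdlog),
    hscrp = stats::rlnorm(n, params$hscrp_meanlog, params$hscrp_sdlog),
    stringsAsFactors = FALSE
  )
  t_max <- params$max_weeks
  list(baseline = baseline,
       u_assign = stats::runif(n),
       u_adh = stats::runif(n),
       u_frailty = stats::runif(n),
       u_pill = matrix(stats::runif(n * t_max), n, t_max),
       u_bleed = matrix(stats::runif(n * t_max), n, t_max),
       u_nausea = matrix(stats::runif(n * t_max), n, t_max),
       u_preg = matrix(stats::runif(n * t_max), n, t_max))
}

# fixed standardizations used by the weekly linear predictors
dgp_standardized <- function(params, baseline) {
  list(age_std = (baseline$age - params$age_mean) / params$age_sd,
       bmi_std = (log(baseline$bmi) - params$bmi_meanlog) / params$bmi_sdlog,
       hscrp_std = (log(baseline$hscrp) - params$hscrp_meanlog) / params$hscrp_sdlog,
       months_trying_std = (log(baseline$months_trying) - params$months_trying_meanlog) /
         params$months_trying_sdlog)
}

# Weekly trajectory under a fixed arm (0 = placebo, 1 = aspirin).
# Everything is vectorized over women; binomial day counts are generated by
# quantile coupling (qbinom on a shared uniform) so the two arms move together.
simulate_arm <- function(params, pop, arm) {
  b <- pop$baseline
  n <- nrow(b)
  t_max <- params$max_weeks
  std <- dgp_standardized(params, b)
  ac <- params$adherence_coefs
  sc <- params$side_effect_coefs
  oc <- params$outcome_coefs

  frailty <- params$adherence_frailty_sd * stats::qnorm(pop$u_frailty)
  adh_base <- ac[["intercept"]] +
    ac[["white"]] * b$white + ac[["hs_education"]] * b$hs_education +
    ac[["married"]] * b$married + ac[["income_ge_40k"]] * b$income_ge_40k +
    ac[["smoked_past_year"]] * b$smoked_past_year +
    ac[["age_std"]] * std$age_std +
    ac[["noise_sd"]] * stats::qnorm(pop$u_adh) + frailty
  p_bleed <- stats::plogis(sc[["bleed_intercept"]] + sc[["bleed_arm"]] * arm +
                             sc[["bleed_hscrp_std"]] * std$hscrp_std)
  p_nausea <- stats::plogis(sc[["nausea_intercept"]] + sc[["nausea_bmi_std"]] * std$bmi_std)
  haz_base <- oc[["intercept"]] +
    oc[["age_std"]] * std$age_std + oc[["bmi_std"]] * std$bmi_std +
    oc[["hscrp_std"]] * std$hscrp_std +
    oc[["smoked_past_year"]] * b$smoked_past_year +
    oc[["months_trying_std"]] * std$months_trying_std +
    oc[["prior_losses_2"]] * (b$prior_losses == 2) +
    params$frailty_outcome_coef * frailty

  pill <- bleed <- nausea <- matrix(0L, n, t_max)
  preg_week <- rep(NA_integer_, n)
  at_risk <- rep(TRUE, n)
  prev_bleed <- rep(0L, n)
  for (t in seq_len(t_max)) {
    bleed[, t] <- stats::qbinom(pop$u_bleed[, t], 7, p_bleed)
    nausea[, t] <- stats::qbinom(pop$u_nausea[, t], 7, p_nausea)
    rho <- stats::plogis(adh_base + ac[["week"]] * (t - 1) +
                           ac[["prev_bleeding"]] * (prev_bleed >= 1))
    pill[, t] <- stats::qbinom(pop$u_pill[, t], 7, rho)
    ingest <- arm * (pill[, t] >= params$ingestion_threshold)
    haz <- stats::plogis(haz_base + oc[["treat"]] * ingest)
    event <- at_risk & (pop$u_preg[, t] < haz)
    preg_week[event] <- t
    at_risk[event] <- FALSE
    prev_bleed <- bleed[, t]
  }
  n_weeks <- ifelse(is.na(preg_week), t_max, preg_week)
  list(pill = pill, bleed = bleed, nausea = nausea,
       preg_week = preg_week, n_weeks = n_weeks,
       y = as.integer(!is.na(preg_week)))
}

# time-fixed adherence of a simulated trajectory under protocol p
traj_adherent <- function(traj, p) {
  wk_idx <- col(traj$pill)
  in_window <- wk_idx <= traj$n_weeks
  adh_weeks <- rowSums((traj$pill >= p$d) & in_window)
  as.integer(adh_weeks / traj$n_weeks >= p$f)
}

#' Simulate a trial
#'
#' Draws a full synthetic trial from the data-generating process: baseline
#' covariates, randomized assignment, weekly pill-taking / bleeding / nausea
#' records, and the hCG-detected pregnancy outcome. Deterministic given
#' `(params, seed)`.
#'
#' @param params a [dgp_params()].
#' @param seed integer; defaults to `params$seed`.
#' @return A [pp_trial()].
#' @export
simulate_trial <- function(params = dgp_params(), seed = params$seed) {
  validate_dgp_params(params)
  with_seed(seed, {
    pop <- draw_population(params, params$n_participants)
    arm <- as.integer(pop$u_assign < params$p_assign)
    t1 <- simulate_arm(params, pop, 1L)
    t0 <- simulate_arm(params, pop, 0L)
    pick <- function(f1, f0) ifelse(arm == 1L, f1, f0)
    n_weeks <- pick(t1$n_weeks, t0$n_weeks)
    baseline <- pop$baseline
    baseline$arm <- ifelse(arm == 1L, "aspirin", "placebo")
    baseline$outcome_hcg <- pick(t1$y, t0$y)
    baseline$pregnancy_week <- as.integer(pick(t1$preg_week, t0$preg_week))
    n <- nrow(baseline)
    idx <- rep(seq_len(n), n_weeks)
    week <- sequence(n_weeks)
    flat <- function(m1, m0) {
      m <- m1
      m[arm == 0L, ] <- m0[arm == 0L, ]
      m[cbind(idx, week)]
    }
    weekly <- data.frame(id = baseline$id[idx], week = as.integer(week),
                         pill_days = as.integer(flat(t1$pill, t0$pill)),
                         bleeding_days = as.integer(flat(t1$bleed, t0$bleed)),
                         nausea_days = as.integer(flat(t1$nausea, t0$nausea)))
    pp_trial(baseline, weekly)
  })
}

#' Monte-Carlo oracle for the true estimands
#'
#' Simulates `n_mc` women with shared random draws under forced aspirin and
#' forced placebo, giving both potential outcomes `Y(1)` and `Y(0)` per
#' woman. The ITT truth is `mean(Y(1)) - mean(Y(0))`; the per-protocol truth
#' restricts the average to women whose factual (assigned-arm) adherence
#' indicator under protocol `p` equals 1. A joint-adherer variant (adherent
#' under both arms) is reported alongside.
#'
#' @param params a [dgp_params()].
#' @param p a [protocol()].
#' @param n_mc Monte-Carlo replicates (>= 1e4).
#' @param seed integer seed.
#' @return List of class `true_estimands` with elements `protocol`,
#'   `true_rd_pp`, `true_rr_pp`, `true_rd_itt`, `true_rr_itt`,
#'   `true_rd_pp_joint`, `true_rr_pp_joint`, `adherent_fraction`,
#'   `mc_se` (of `true_rd_pp`), `mc_se_itt`, and `n_mc`.
#' @export
true_estimands <- function(params = dgp_params(), p = protocol(),
                           n_mc = 1e5, seed = params$seed) {
  validate_dgp_params(params)
  if (n_mc < 1e4) stopf("n_mc must be at least 10^4")
  with_seed(seed, {
    pop <- draw_population(params, as.integer(n_mc))
    t1 <- simulate_arm(params, pop, 1L)
    t0 <- simulate_arm(params, pop, 0L)
    a <- as.integer(pop$u_assign < params$p_assign)
    c1 <- traj_adherent(t1, p)
    c0 <- traj_adherent(t0, p)
    cf <- ifelse(a == 1L, c1, c0)
    d <- t1$y - t0$y
    sel <- cf == 1L
    joint <- c1 == 1L & c0 == 1L
    rr <- function(s) mean(t1$y[s]) / mean(t0$y[s])
    structure(list(
      protocol = p,
      true_rd_pp = mean(d[sel]),
      true_rr_pp = rr(sel),
      true_rd_itt = mean(d),
      true_rr_itt = mean(t1$y) / mean(t0$y),
      true_rd_pp_joint = mean(d[joint]),
      true_rr_pp_joint = rr(joint),
      adherent_fraction = mean(cf),
      mc_se = stats::sd(d[sel]) / sqrt(sum(sel)),
      mc_se_itt = stats::sd(d) / sqrt(length(d)),
      n_mc = as.integer(n_mc)), class = "true_estimands")
  })
}

#' @export
print.true_estimands <- function(x, ...) {
  cat(sprintf("<true estimands> protocol (%d, %.2f), n_mc = %d\n",
              x$protocol$d, x$protocol$f, x$n_mc))
  cat(sprintf("  per-protocol RD %.4f (mc se %.4f), RR %.3f; joint-adherer RD %.4f\n",
              x$true_rd_pp, x$mc_se, x$true_rr_pp, x$true_rd_pp_joint))
  cat(sprintf("  ITT          RD %.4f (mc se %.4f), RR %.3f; adherent fraction %.3f\n",
              x$true_rd_itt, x$mc_se_itt, x$true_rr_itt, x$adherent_fraction))
  invisible(x)
}
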