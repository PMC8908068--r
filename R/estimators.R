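#' @name estimators
#' @title Effect estimators for the adherence-adjusted analysis
#'
#' @description
#' All estimators operate on the analytic rows of [build_analytic()] (or any
#' data frame with `A`, `Y` and covariate columns recorded in the
#' `"covariates"` attribute) and return a two-row data frame of class
#' `pp_estimates`: the effect on the risk-difference and risk-ratio scales
#' with influence-function (or bootstrap) standard errors and Wald 95%
#' confidence intervals (normal quantile 1.96; risk ratios on the log
#' scale, exponentiated).
NULL

estimate_frame <- function(estimand, method, rd, rd_se, rr, log_rr_se, n) {
  z <- stats::qnorm(0.975)
  out <- data.frame(
    estimand = estimand, method = method,
    scale = c("risk_difference", "risk_ratio"),
    point = c(rd, rr),
    se = c(rd_se, rr * log_rr_se),
    ci_lower = c(rd - z * rd_se, exp(log(rr) - z * log_rr_se)),
    ci_upper = c(rd + z * rd_se, exp(log(rr) + z * log_rr_se)),
    n_used = as.integer(n))
  class(out) <- c("pp_estimates", "data.frame")
  out
}

rows_xay <- function(rows, extra_covariates = character(0)) {
  covs <- c(attr(rows, "covariates") %||% encoded_covariate_names(), extra_covariates)
  missing <- setdiff(covs, names(rows))
  if (length(missing)) stopf("analytic rows lack covariates: %s", paste(missing, collapse = ", "))
  list(W = as.matrix(rows[, covs, drop = FALSE]), A = rows$A, Y = rows$Y)
}

#' Cross-fit nuisance predictions
#'
#' Splits the rows into `k` folds; for each fold, a propensity stack
#' (exposure on covariates) and an outcome stack (outcome on covariates and
#' exposure) are trained on the other k-1 folds and evaluated on the
#' held-out fold, so every row's `pi_hat`, `mu1_hat` (outcome prediction
#' with exposure set to 1) and `mu0_hat` come from models not trained on
#' it. Propensity predictions are truncated to `truncation_bounds`. If a
#' training split lacks an exposure class the folds are re-randomized (up
#' to 10 attempts) before failing.
#'
#' @param rows analytic data frame ([build_analytic()]).
#' @param specs learner library for both stacks (list of [learner_spec()]).
#' @param k cross-fitting folds (>= 2).
#' @param v internal cross-validation folds of each stack.
#' @param truncation_bounds length-2 numeric, propensity truncation.
#' @param seed integer seed (fold assignment + stack randomness).
#' @param extra_covariates extra column names (e.g. the postrandomization
#'   flags) appended to the covariate set.
#' @return Object of class `pp_nuisances`: `pi_hat`, `mu1_hat`, `mu0_hat`,
#'   `fold_ids`, `truncation_bounds`, `n_truncated`, `propensity_weights`
#'   and `outcome_weights` (per-fold meta-weight matrices).
#' @export
cross_fit_nuisances <- function(rows, specs = glm_learners(), k = 5L, v = 10L,
                                truncation_bounds = c(0.025, 0.975), seed = 1L,
                                extra_covariates = character(0)) {
  if (k < 2L) stopf("k must be >= 2")
  d <- rows_xay(rows, extra_covariates)
  n <- nrow(d$W)
  fold_ids <- NULL
  for (attempt in seq_len(10L)) {
    cand <- with_seed(seed + attempt - 1L, sample(rep(seq_len(k), length.out = n)))
    ok <- all(vapply(seq_len(k), function(f) length(unique(d$A[cand != f])) == 2L, logical(1)))
    if (ok) { fold_ids <- cand; break }
    message(sprintf("fold attempt %d left a training split without both exposure classes; re-randomizing", attempt))
  }
  if (is.null(fold_ids)) stopf("could not build folds with both exposure classes in every training split")
  pi_hat <- mu1 <- mu0 <- numeric(n)
  pw <- ow <- list()
  XA <- cbind(d$W, A = d$A)
  for (f in seq_len(k)) {
    test <- fold_ids == f
    tr <- !test
    ps <- fit_stack(d$W[tr, , drop = FALSE], d$A[tr], specs, v = v, seed = seed + 100L * f)
    os <- fit_stack(XA[tr, , drop = FALSE], d$Y[tr], specs, v = v, seed = seed + 100L * f + 50L)
    pi_hat[test] <- predict_stack(ps, d$W[test, , drop = FALSE])
    X1 <- X0 <- XA[test, , drop = FALSE]
    X1[, "A"] <- 1; X0[, "A"] <- 0
    mu1[test] <- predict_stack(os, X1)
    mu0[test] <- predict_stack(os, X0)
    pw[[f]] <- ps$meta_weights
    ow[[f]] <- os$meta_weights
  }
  n_trunc <- sum(pi_hat < truncation_bounds[1] | pi_hat > truncation_bounds[2])
  if (n_trunc > 0)
    message(sprintf("propensity truncation active for %d of %d rows (bounds %.3f-%.3f)",
                    n_trunc, n, truncation_bounds[1], truncation_bounds[2]))
  pi_hat <- pmin(pmax(pi_hat, truncation_bounds[1]), truncation_bounds[2])
  structure(list(pi_hat = pi_hat, mu1_hat = clip01(mu1), mu0_hat = clip01(mu0),
                 fold_ids = fold_ids, truncation_bounds = truncation_bounds,
                 n_truncated = n_trunc,
                 propensity_weights = do.call(rbind, pw),
                 outcome_weights = do.call(rbind, ow)),
            class = "pp_nuisances")
}

#' Augmented inverse probability weighting
#'
#' Doubly robust estimator built from per-row pseudo-outcomes
#' `psi1 = A (Y - mu1) / pi + mu1` and
#' `psi0 = (1 - A) (Y - mu0) / (1 - pi) + mu0`. The risk difference is
#' `mean(psi1 - psi0)` with SE `sd(psi1 - psi0) / sqrt(n)`; the risk ratio
#' is `mean(psi1) / mean(psi0)` with a delta-method SE on the log scale
#' from the influence function of the log ratio.
#'
#' @param rows analytic data frame.
#' @param nu a [cross_fit_nuisances()] object aligned to `rows`.
#' @param estimand label carried into the output.
#' @return A `pp_estimates` data frame (risk difference and risk ratio).
#' @export
aipw <- function(rows, nu, estimand = "per_protocol") {
  d <- rows_xay(rows)
  n <- length(d$A)
  if (any(nu$pi_hat <= 0) || any(nu$pi_hat >= 1)) stopf("pi_hat must lie strictly in (0,1); truncate first")
  psi1 <- d$A * (d$Y - nu$mu1_hat) / nu$pi_hat + nu$mu1_hat
  psi0 <- (1 - d$A) * (d$Y - nu$mu0_hat) / (1 - nu$pi_hat) + nu$mu0_hat
  rd <- mean(psi1 - psi0)
  rd_se <- stats::sd(psi1 - psi0) / sqrt(n)
  m1 <- mean(psi1); m0 <- mean(psi0)
  if_log <- psi1 / m1 - psi0 / m0
  estimate_frame(estimand, "aipw", rd, rd_se, m1 / m0, stats::sd(if_log) / sqrt(n), n)
}

#' Targeted maximum likelihood estimation
#'
#' Updates the initial outcome predictions along a two-parameter logistic
#' fluctuation with clever covariates `H1 = A / pi` and
#' `H0 = (1 - A) / (1 - pi)` (intercept-free logistic regression of the
#' outcome with offset `logit(mu_A)`), then plugs the targeted predictions
#' into the standardization formulas. Variance comes from the efficient
#' influence function. A non-convergent fluctuation falls back to zero
#' fluctuation (a message is emitted), in which case TMLE equals
#' g-computation on the same outcome fits.
#'
#' @inheritParams aipw
#' @return A `pp_estimates` data frame; the attribute `"eif_mean"` records
#'   the post-targeting efficient-influence-function sample mean for the
#'   risk difference (should be ~0).
#' @export
tmle <- function(rows, nu, estimand = "per_protocol") {
  d <- rows_xay(rows)
  n <- length(d$A)
  H1 <- d$A / nu$pi_hat
  H0 <- (1 - d$A) / (1 - nu$pi_hat)
  off <- stats::qlogis(ifelse(d$A == 1, nu$mu1_hat, nu$mu0_hat))
  eps <- tryCatch({
    fit <- suppressWarnings(stats::glm(d$Y ~ 0 + H1 + H0 + offset(off),
                                       family = stats::binomial(),
                                       control = stats::glm.control(epsilon = 1e-12, maxit = 200)))
    if (!fit$converged) stop("fluctuation did not converge")
    stats::coef(fit)
  }, error = function(e) {
    message("TMLE fluctuation failed (", conditionMessage(e), "); using zero fluctuation")
    c(H1 = 0, H0 = 0)
  })
  mu1s <- stats::plogis(stats::qlogis(nu$mu1_hat) + eps[["H1"]] / nu$pi_hat)
  mu0s <- stats::plogis(stats::qlogis(nu$mu0_hat) + eps[["H0"]] / (1 - nu$pi_hat))
  m1 <- mean(mu1s); m0 <- mean(mu0s)
  rd <- m1 - m0
  eif1 <- H1 * (d$Y - mu1s) + mu1s - m1
  eif0 <- H0 * (d$Y - mu0s) + mu0s - m0
  eif_rd <- eif1 - eif0
  if_log <- eif1 / m1 - eif0 / m0
  out <- estimate_frame(estimand, "tmle", rd, stats::sd(eif_rd) / sqrt(n),
                        m1 / m0, stats::sd(if_log) / sqrt(n), n)
  attr(out, "eif_mean") <- mean(eif_rd)
  attr(out, "targeted_mu") <- list(mu1 = mu1s, mu0 = mu0s)
  out
}

#' G-computation (standardization)
#'
#' Main-effects logistic outcome regression on exposure and covariates;
#' predictions are standardized over the empirical covariate distribution
#' with exposure set to 1 and 0. Standard errors by seeded nonparametric
#' bootstrap.
#'
#' @inheritParams aipw
#' @param boot bootstrap replicates.
#' @param seed integer seed for the bootstrap.
#' @param extra_covariates extra adjustment columns.
#' @return A `pp_estimates` data frame.
#' @export
gcomp <- function(rows, estimand = "per_protocol", boot = 1000L, seed = 1L,
                  extra_covariates = character(0)) {
  d <- rows_xay(rows, extra_covariates)
  point <- gcomp_point(d)
  bt <- with_seed(seed, {
    vapply(seq_len(boot), function(b) {
      i <- sample.int(length(d$A), replace = TRUE)
      gcomp_point(list(W = d$W[i, , drop = FALSE], A = d$A[i], Y = d$Y[i]))
    }, numeric(2))
  })
  estimate_frame(estimand, "gcomp", point[1], stats::sd(bt[1, ]),
                 exp(point[2]), stats::sd(bt[2, ]), length(d$A))
}

# returns c(risk difference, log risk ratio)
gcomp_point <- function(d) {
  D <- cbind(A = d$A, d$W)
  cf <- glm_design_fit(D, d$Y)
  D1 <- D0 <- D
  D1[, "A"] <- 1; D0[, "A"] <- 0
  m1 <- mean(glm_design_predict(cf, D1))
  m0 <- mean(glm_design_predict(cf, D0))
  c(m1 - m0, log(m1 / m0))
}

#' Inverse probability weighting
#'
#' Main-effects logistic propensity model; Hajek (normalized) weighted
#' means with weights `A / pi + (1 - A) / (1 - pi)`, with robust
#' (influence-function sandwich) standard errors treating the weights as
#' known, which is conservative for an estimated propensity.
#'
#' @inheritParams aipw
#' @param truncation_bounds propensity truncation bounds.
#' @param extra_covariates extra adjustment columns.
#' @return A `pp_estimates` data frame.
#' @export
ipw <- function(rows, estimand = "per_protocol",
                truncation_bounds = c(0.025, 0.975), extra_covariates = character(0)) {
  d <- rows_xay(rows, extra_covariates)
  n <- length(d$A)
  cf <- glm_design_fit(d$W, d$A)
  pi_hat <- pmin(pmax(glm_design_predict(cf, d$W), truncation_bounds[1]), truncation_bounds[2])
  w1 <- d$A / pi_hat
  w0 <- (1 - d$A) / (1 - pi_hat)
  m1 <- sum(w1 * d$Y) / sum(w1)
  m0 <- sum(w0 * d$Y) / sum(w0)
  if1 <- w1 * (d$Y - m1) / mean(w1)
  if0 <- w0 * (d$Y - m0) / mean(w0)
  rd_se <- stats::sd(if1 - if0) / sqrt(n)
  if_log <- if1 / m1 - if0 / m0
  estimate_frame(estimand, "ipw", m1 - m0, rd_se, m1 / m0,
                 stats::sd(if_log) / sqrt(n), n)
}

#' Unadjusted contrast
#'
#' Arm-specific risks from the 2 x 2 table; binomial standard errors for
#' the risk difference and the delta-method SE for the log risk ratio.
#'
#' @inheritParams aipw
#' @return A `pp_estimates` data frame.
#' @export
unadjusted <- function(rows, estimand = "per_protocol") {
  d <- rows_xay(rows)
  n1 <- sum(d$A == 1); n0 <- sum(d$A == 0)
  if (n1 == 0 || n0 == 0) stopf("both exposure groups must be present")
  p1 <- mean(d$Y[d$A == 1]); p0 <- mean(d$Y[d$A == 0])
  rd_se <- sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0)
  log_rr_se <- sqrt((1 - p1) / (n1 * p1) + (1 - p0) / (n0 * p0))
  estimate_frame(estimand, "unadjusted", p1 - p0, rd_se, p1 / p0, log_rr_se, n1 + n0)
}

#' @export
print.pp_estimates <- function(x, ...) {
  df <- as.data.frame(x)
  df$point <- round(df$point, 4); df$se <- round(df$se, 4)
  df$ci_lower <- round(df$ci_lower, 4); df$ci_upper <- round(df$ci_upper, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
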