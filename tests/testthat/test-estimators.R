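make_nuisances <- function(pi_hat, mu1, mu0, n) {
  structure(list(pi_hat = rep(pi_hat, length.out = n),
                 mu1_hat = rep(mu1, length.out = n),
                 mu0_hat = rep(mu0, length.out = n),
                 fold_ids = rep(1L, n), truncation_bounds = c(0, 1),
                 n_truncated = 0L), class = "pp_nuisances")
}

test_that("AIPW with constant nuisances reduces exactly to the unadjusted contrast", {
  set.seed(61)
  rows <- constant_covariate_rows(A = rbinom(300, 1, 0.45), Y = rbinom(300, 1, 0.5))
  nu <- make_nuisances(mean(rows$A), mean(rows$Y), mean(rows$Y), nrow(rows))
  a <- aipw(rows, nu)
  u <- unadjusted(rows)
  expect_equal(a$point[1], u$point[1], tolerance = 1e-12)
  expect_equal(a$point[2], u$point[2], tolerance = 1e-12)
  expect_error(aipw(rows, make_nuisances(0, 0.5, 0.5, nrow(rows))), "truncate")
})

test_that("unadjusted risks and delta-method SEs match hand computation", {
  # balanced null table: 50/100 events in each arm
  rows0 <- constant_covariate_rows(A = rep(c(1, 0), each = 100),
                                   Y = rep(c(1, 0, 1, 0), each = 50))
  u0 <- unadjusted(rows0)
  expect_equal(u0$point[1], 0)
  expect_equal(u0$point[2], 1)
  # hand table: treated 30/80 events, control 18/90
  rows1 <- constant_covariate_rows(A = rep(c(1, 0), c(80, 90)),
                                   Y = c(rep(1, 30), rep(0, 50), rep(1, 18), rep(0, 72)))
  u1 <- unadjusted(rows1)
  p1 <- 30 / 80; p0 <- 18 / 90
  expect_equal(u1$point[1], p1 - p0, tolerance = 1e-12)
  expect_equal(u1$se[1], sqrt(p1 * (1 - p1) / 80 + p0 * (1 - p0) / 90), tolerance = 1e-12)
  log_rr_se <- sqrt((1 - p1) / (80 * p1) + (1 - p0) / (90 * p0))
  expect_equal(u1$se[2], (p1 / p0) * log_rr_se, tolerance = 1e-12)
  expect_equal(u1$ci_upper[2], exp(log(p1 / p0) + qnorm(0.975) * log_rr_se), tolerance = 1e-12)
  expect_true(all(u1$ci_lower <= u1$point & u1$point <= u1$ci_upper))
})

test_that("TMLE with a saturated initial fit has zero fluctuation and equals the plug-in", {
  # one binary covariate; nuisances are the exact cell means, so the
  # fluctuation score is already solved and epsilon = 0
  cells <- expand.grid(A = 0:1, W = 0:1)
  counts <- c(40, 35, 30, 45); events <- c(10, 20, 9, 30)
  A <- rep(cells$A, counts); W <- rep(cells$W, counts)
  Y <- unlist(mapply(function(n, e) c(rep(1, e), rep(0, n - e)), counts, events,
                     SIMPLIFY = FALSE))
  rows <- data.frame(A = A, Y = Y, w1 = W)
  attr(rows, "covariates") <- "w1"
  mu <- function(a, w) {
    i <- cells$A == a & cells$W == w
    events[i] / counts[i]
  }
  pi_w <- function(w) {
    tr <- cells$A == 1 & cells$W == w; al <- cells$W == w
    sum(counts[tr]) / sum(counts[al])
  }
  nu <- structure(list(pi_hat = vapply(W, pi_w, 0),
                       mu1_hat = vapply(W, function(w) mu(1, w), 0),
                       mu0_hat = vapply(W, function(w) mu(0, w), 0),
                       fold_ids = rep(1L, length(A)),
                       truncation_bounds = c(0, 1), n_truncated = 0L),
                  class = "pp_nuisances")
  tm <- tmle(rows, nu)
  plug_in <- mean(nu$mu1_hat) - mean(nu$mu0_hat)
  expect_equal(tm$point[1], plug_in, tolerance = 1e-9)
  expect_lt(abs(attr(tm, "eif_mean")), 1e-9)
  # exact standardization by hand over the W margin
  pw1 <- mean(W)
  hand <- (mu(1, 1) - mu(0, 1)) * pw1 + (mu(1, 0) - mu(0, 0)) * (1 - pw1)
  expect_equal(tm$point[1], hand, tolerance = 1e-9)
  mus <- attr(tm, "targeted_mu")
  expect_true(all(mus$mu1 >= 0 & mus$mu1 <= 1 & mus$mu0 >= 0 & mus$mu0 <= 1))
})

test_that("g-computation matches an independent formula-interface standardization", {
  set.seed(71)
  n <- 400
  W <- rbinom(n, 1, 0.4)
  A <- rbinom(n, 1, plogis(-0.3 + 0.8 * W))
  Y <- rbinom(n, 1, plogis(-0.5 + 0.7 * A + 0.6 * W))
  rows <- data.frame(A = A, Y = Y, w1 = W)
  attr(rows, "covariates") <- "w1"
  g <- gcomp(rows, boot = 200, seed = 72)
  # oracle route: formula glm + predict + manual averaging
  fit <- glm(Y ~ A + w1, family = binomial(), data = rows)
  m1 <- mean(predict(fit, transform(rows, A = 1), type = "response"))
  m0 <- mean(predict(fit, transform(rows, A = 0), type = "response"))
  expect_equal(g$point[1], m1 - m0, tolerance = 1e-8)
  expect_equal(g$point[2], m1 / m0, tolerance = 1e-8)
  expect_true(g$ci_lower[1] <= g$point[1] && g$point[1] <= g$ci_upper[1])
  expect_gt(g$se[1], 0)
  # null-effect data: estimate near zero
  Y0 <- rbinom(n, 1, plogis(-0.5 + 0.6 * W))
  rows0 <- data.frame(A = A, Y = Y0, w1 = W)
  attr(rows0, "covariates") <- "w1"
  g0 <- gcomp(rows0, boot = 200, seed = 73)
  expect_lt(abs(g0$point[1]), 3 * g0$se[1] + 0.02)
})

test_that("IPW with a constant propensity equals the unadjusted estimator", {
  set.seed(81)
  rows <- constant_covariate_rows(A = rbinom(250, 1, 0.5), Y = rbinom(250, 1, 0.45))
  i <- ipw(rows)
  u <- unadjusted(rows)
  expect_equal(i$point[1], u$point[1], tolerance = 1e-8)
  expect_equal(i$point[2], u$point[2], tolerance = 1e-8)
  # weights are positive and IPW recovers a known logistic-linear propensity DGP
  n <- 20000
  W <- rnorm(n)
  A <- rbinom(n, 1, plogis(0.5 * W))
  Y <- rbinom(n, 1, plogis(-0.8 + 0.5 * A + 0.7 * W))
  rows2 <- data.frame(A = A, Y = Y, w1 = W)
  attr(rows2, "covariates") <- "w1"
  est <- ipw(rows2)
  truth <- mean(plogis(-0.8 + 0.5 + 0.7 * W)) - mean(plogis(-0.8 + 0.7 * W))
  expect_lt(abs(est$point[1] - truth), 3 * est$se[1])
})

test_that("cross-fitting honors the partition, bounds and randomization", {
  an <- build_analytic(sim_trial_cached(600, 101))
  rows <- subset_rows(an, an$C == 1L)
  nu <- cross_fit_nuisances(rows, glm_learners(), k = 2, v = 5, seed = 91)
  expect_equal(sort(unique(nu$fold_ids)), 1:2)
  # dual-route audit: refit each fold's models by hand and compare
  d <- rows_xay(rows)
  XA <- cbind(d$W, A = d$A)
  for (f in 1:2) {
    test <- nu$fold_ids == f
    ps <- fit_stack(d$W[!test, , drop = FALSE], d$A[!test], glm_learners(),
                    v = 5, seed = 91 + 100 * f)
    pi_manual <- pmin(pmax(predict_stack(ps, d$W[test, , drop = FALSE]), 0.025), 0.975)
    expect_equal(nu$pi_hat[test], pi_manual, tolerance = 1e-10)
  }
  expect_true(all(nu$pi_hat >= 0.025 & nu$pi_hat <= 0.975))
  expect_true(all(nu$mu1_hat > 0 & nu$mu1_hat < 1))
  # randomized design: mean propensity near the treated fraction
  nu5 <- cross_fit_nuisances(rows, glm_learners(), k = 5, v = 5, seed = 92)
  expect_lt(abs(mean(nu5$pi_hat) - mean(rows$A)), 0.05)
  expect_error(cross_fit_nuisances(rows, glm_learners(), k = 1), ">= 2")
})

test_that("the estimator battery emits the full method-by-scale report", {
  tr <- sim_trial_cached(600, 101)
  est <- suppressMessages(
    estimate_battery(tr, protocol(5, 0.8), specs = glm_learners(),
                     k = 3, v = 3, boot = 100, seed = 61))
  expect_equal(nrow(est), 5 * 2 * 2)  # methods x scales x estimands
  expect_setequal(unique(est$method), c("aipw", "tmle", "gcomp", "ipw", "unadjusted"))
  expect_setequal(unique(est$estimand), c("itt", "per_protocol"))
  expect_true(all(est$ci_lower <= est$point & est$point <= est$ci_upper))
  expect_true(all(est$se > 0))
  expect_true(all(est$point[est$scale == "risk_ratio"] > 0))
  n_pp <- sum(build_analytic(tr)$C)
  expect_true(all(est$n_used[est$estimand == "per_protocol"] == n_pp))
  # postrandomization variant runs and reports the same shape
  est2 <- suppressMessages(
    estimate_battery(tr, protocol(5, 0.8), methods = c("gcomp", "ipw"),
                     estimands = "per_protocol", specs = glm_learners(),
                     boot = 50, seed = 62, adjust_postrandomization = TRUE))
  expect_equal(nrow(est2), 4)
})

test_that("near-universal adherence collapses per-protocol and ITT estimates", {
  ac <- dgp_params()$adherence_coefs
  ac[["intercept"]] <- 30; ac[["noise_sd"]] <- 0; ac[["week"]] <- 0
  ac[["prev_bleeding"]] <- 0
  tr <- simulate_trial(dgp_params(n_participants = 2000, adherence_coefs = ac), seed = 63)
  an <- build_analytic(tr)
  expect_gt(mean(an$C), 0.999)
  est <- suppressMessages(
    estimate_battery(tr, methods = "aipw", specs = glm_learners(), k = 3, v = 3,
                     seed = 64))
  rd <- est$point[est$scale == "risk_difference"]
  se <- est$se[est$scale == "risk_difference"]
  expect_lt(abs(rd[1] - rd[2]), 2 * max(se))
})
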