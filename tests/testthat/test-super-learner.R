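# exact NNLS oracle: enumerate supports, solve least squares on each,
# keep nonnegative solutions, take the best objective
nnls_oracle_objective <- function(Z, y) {
  k <- ncol(Z)
  best <- sum(y^2)  # empty support
  for (size in 1:k) for (S in asplit(combn(k, size), 2)) {
    cf <- qr.coef(qr(Z[, S, drop = FALSE]), y)
    cf[is.na(cf)] <- 0
    if (all(cf >= -1e-12)) best <- min(best, sum((y - Z[, S, drop = FALSE] %*% cf)^2))
  }
  best
}

test_that("NNLS solves the nonnegative least squares problem exactly", {
  set.seed(42)
  for (i in 1:20) {
    Z <- matrix(runif(50 * 3), 50, 3)
    y <- rbinom(50, 1, Z[, 1] * 0.6 + 0.2)
    b <- nnls_solve(Z, y)
    expect_true(all(b >= 0))
    expect_equal(sum((y - Z %*% b)^2), nnls_oracle_objective(Z, y), tolerance = 1e-8)
  }
  # the cone optimum is never worse than the best simplex-grid point
  set.seed(43)
  Z <- matrix(runif(50 * 3), 50, 3); y <- rbinom(50, 1, 0.5)
  b <- nnls_solve(Z, y)
  grid <- expand.grid(b1 = seq(0, 1, 0.01), b2 = seq(0, 1, 0.01))
  grid <- grid[grid$b1 + grid$b2 <= 1, ]
  simplex_best <- min(apply(grid, 1, function(g)
    sum((y - Z %*% c(g[1], g[2], 1 - g[1] - g[2]))^2)))
  expect_lte(sum((y - Z %*% b)^2), simplex_best + 1e-9)
})

test_that("meta-weights live on the simplex and behave under exact/duplicate columns", {
  set.seed(7)
  y <- rbinom(80, 1, 0.5)
  Z <- cbind(y, runif(80), runif(80))
  w <- nnls_meta_weights(Z, y)
  expect_equal(w[1], 1, tolerance = 1e-8)
  expect_equal(sum(w), 1)
  # duplicated columns: weights may split but fitted values are unchanged
  z1 <- clip01(0.3 * y + 0.35 + 0.1 * runif(80))
  Zd <- cbind(z1, z1)
  wd <- nnls_meta_weights(Zd, y)
  expect_equal(sum(wd), 1)
  single <- nnls_solve(matrix(z1), y)
  expect_equal(as.numeric(Zd %*% (wd * sum(nnls_solve(Zd, y)))),
               as.numeric(z1 * single), tolerance = 1e-6)
  # anti-correlated column: all-zero solution falls back to one learner
  y2 <- c(1, 1, 1, 0, 0, 0)
  Zneg <- matrix(1 - y2)
  expect_message(wz <- nnls_meta_weights(Zneg, y2, cv_risks = 1), "all-zero")
  expect_equal(wz, 1)
  expect_error(nnls_solve(matrix(0, 5, 2), rnorm(5)), "rank 0")
})

test_that("level-one predictions are strictly out of fold", {
  set.seed(13)
  X <- matrix(rnorm(100 * 3), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(100, 1, plogis(X[, 1]))
  lv1 <- cv_level_one(X, y, list(mean_learner(), learner_spec("glm_main")),
                      v = 10, seed = 31)
  expect_equal(dim(lv1$Z), c(100, 2))
  expect_equal(sort(unique(lv1$fold_ids)), 1:10)
  # the constant-mean learner's column must equal its training-fold mean,
  # which proves each row was predicted by a model that never saw it
  for (f in 1:10) {
    test <- lv1$fold_ids == f
    expect_equal(unique(lv1$Z[test, 1]), mean(y[!test]), tolerance = 1e-9)
  }
  # an oracle learner that knows the true probabilities attains minimal CV log-loss
  specs <- list(oracle_learner(function(X) plogis(X[, 1])),
                mean_learner(), learner_spec("glm_two_way"))
  lv2 <- cv_level_one(X, y, specs, v = 5, seed = 32)
  risks <- -colMeans(y * log(lv2$Z) + (1 - y) * log(1 - lv2$Z))
  expect_equal(unname(which.min(risks)), 1L)
  # degenerate outcome: training folds with one class collapse to the fold mean
  y0 <- rep(0L, 100)
  expect_message(lv3 <- cv_level_one(X, y0, list(learner_spec("glm_main")), v = 5,
                                     seed = 33), "single outcome class")
  expect_true(all(lv3$Z <= 1e-6))
})

test_that("the stack is a simplex combination that predicts no worse than its parts", {
  set.seed(17)
  n <- 500
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("x", 1:4)))
  truth <- plogis(1.2 * sin(X[, 1]) + X[, 2] * X[, 3])
  y <- rbinom(n, 1, truth)
  specs <- list(learner_spec("glm_main"),
                learner_spec("spl", "mars", tuning_grid = list(degree = c(1, 2))),
                learner_spec("xgb", "gradient_boosting",
                             tuning_grid = list(max_depth = 3, nrounds = 100, eta = 0.1)))
  st <- fit_stack(X, y, specs, v = 5, seed = 51)
  expect_true(all(st$meta_weights >= 0))
  expect_equal(sum(st$meta_weights), 1, tolerance = 1e-12)
  expect_equal(length(st$meta_weights), 4)  # grid expands the spline slot
  # held-out comparison against each single learner refit on all rows
  Xte <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("x", 1:4)))
  tte <- plogis(1.2 * sin(Xte[, 1]) + Xte[, 2] * Xte[, 3])
  yte <- rbinom(n, 1, tte)
  ll <- function(p) -mean(yte * log(pmax(p, 1e-12)) + (1 - yte) * log(pmax(1 - p, 1e-12)))
  stack_ll <- ll(predict_stack(st, Xte))
  single_ll <- vapply(seq_along(st$learner_defs), function(j) {
    m <- fit_learner(st$learner_defs[[j]], X, y, seed = 51 + j)
    ll(clip01(predict_learner(m, Xte)))
  }, numeric(1))
  expect_lte(stack_ll, min(single_ll) + 0.01)
})

test_that("single-learner stacks short-circuit and predictions stay in range", {
  set.seed(23)
  X <- matrix(rnorm(60 * 2), 60, 2, dimnames = list(NULL, c("u", "v")))
  y <- rbinom(60, 1, plogis(X[, 1]))
  st <- fit_stack(X, y, glm_learners(), v = 5, seed = 3)
  expect_equal(st$meta_weights, 1)
  direct <- fit_learner(expand_learners(glm_learners())[[1]], X, y, seed = 4)
  expect_equal(predict_stack(st, X), clip01(predict_learner(direct, X)), tolerance = 1e-12)
  # all-zero outcome: predictions at the clip floor
  st0 <- fit_stack(X, rep(0L, 60), glm_learners(), v = 5, seed = 3)
  expect_true(all(predict_stack(st0, X) <= 1e-6))
  expect_error(predict_stack(st, X[, 1, drop = FALSE]), "columns")
})

test_that("stacking is deterministic given data, specs, folds and seed", {
  set.seed(29)
  X <- matrix(rnorm(150 * 3), 150, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(150, 1, plogis(X[, 1] - X[, 2]))
  specs <- list(learner_spec("glm_main"),
                learner_spec("rf", "random_forest",
                             tuning_grid = list(num_trees = 100, mtry_frac = "sqrt")),
                learner_spec("xgb", "gradient_boosting",
                             tuning_grid = list(max_depth = 2, nrounds = 50, eta = 0.1)))
  s1 <- fit_stack(X, y, specs, v = 5, seed = 77)
  s2 <- fit_stack(X, y, specs, v = 5, seed = 77)
  expect_identical(s1$meta_weights, s2$meta_weights)
  expect_identical(predict_stack(s1, X), predict_stack(s2, X))
  s3 <- fit_stack(X, y, specs, v = 5, seed = 78)
  expect_false(identical(s1$meta_weights, s3$meta_weights))
})
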