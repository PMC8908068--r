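#' Base learner specification
#'
#' Describes one family of base learners for the stack. A non-empty
#' `tuning_grid` expands to one learner per combination of hyperparameter
#' values, so a single spec can contribute several columns to the level-one
#' matrix.
#'
#' Kinds:
#' \describe{
#'   \item{`glm_main`}{logistic regression, main effects only.}
#'   \item{`glm_two_way`}{logistic regression with main effects and all
#'     two-way interactions.}
#'   \item{`mars`}{adaptive nonlinear regression slot. The built-in
#'     implementation is a spline-expanded logistic GLM (natural cubic
#'     splines on continuous covariates; `degree = 2` adds all two-way
#'     interactions of the original covariates), standing in the
#'     multivariate-adaptive-regression-splines position of the stack; a
#'     true MARS learner can be plugged in via `kind = "custom"`.}
#'   \item{`random_forest`}{probability forest via \pkg{ranger}; grid over
#'     `num_trees` and `mtry_frac` (`"sqrt"` or `"third"` of p).}
#'   \item{`gradient_boosting`}{extreme gradient boosting via
#'     \pkg{xgboost}; grid over `max_depth`, `nrounds`, `eta`.}
#'   \item{`custom`}{user-supplied `fit(X, y)` returning an object and
#'     `predict(object, X)` returning probabilities.}
#' }
#'
#' @param name label used in reports.
#' @param kind one of the kinds above.
#' @param tuning_grid named list of hyperparameter values; required
#'   (non-empty) for `mars`, `random_forest` and `gradient_boosting`.
#' @param fit,predict functions for `kind = "custom"`.
#' @return Object of class `learner_spec`.
#' @export
learner_spec <- function(name, kind = name, tuning_grid = list(),
                         fit = NULL, predict = NULL) {
  kinds <- c("glm_main", "glm_two_way", "mars", "random_forest",
             "gradient_boosting", "custom")
  if (!kind %in% kinds) stopf("unknown learner kind '%s'", kind)
  if (kind %in% c("mars", "random_forest", "gradient_boosting") && !length(tuning_grid))
    stopf("kind '%s' requires a non-empty tuning_grid", kind)
  if (kind == "custom" && (!is.function(fit) || !is.function(predict)))
    stopf("custom learners need `fit` and `predict` functions")
  structure(list(name = name, kind = kind, tuning_grid = tuning_grid,
                 fit = fit, predict = predict),
            class = "learner_spec")
}

#' Default learner library
#'
#' The five-family stack: main-effects GLM, all-two-way GLM, the spline
#' nonlinear slot (degree 1 and 2), random forests (500 trees, mtry sqrt(p)
#' or p/3), and gradient boosting (depth 1 or 3, 100 or 500 rounds,
#' learning rate 0.1) - 10 learners after grid expansion.
#'
#' @return List of [learner_spec()] objects.
#' @export
default_learners <- function() {
  list(learner_spec("glm_main"),
       learner_spec("glm_two_way"),
       learner_spec("spline", "mars", tuning_grid = list(degree = c(1, 2))),
       learner_spec("rf", "random_forest",
                    tuning_grid = list(num_trees = 500, mtry_frac = c("sqrt", "third"))),
       learner_spec("xgb", "gradient_boosting",
                    tuning_grid = list(max_depth = c(1, 3), nrounds = c(100, 500),
                                       eta = 0.1)))
}

#' GLM-only learner library (fast, correctly specified for logit-linear
#' nuisance models)
#' @return List with a single main-effects GLM spec.
#' @export
glm_learners <- function() list(learner_spec("glm_main"))

# expand tuning grids: one atomic learner per hyperparameter combination
expand_learners <- function(specs) {
  out <- list()
  for (sp in specs) {
    if (!inherits(sp, "learner_spec")) stopf("specs must be learner_spec objects")
    if (!length(sp$tuning_grid)) {
      out[[length(out) + 1L]] <- list(name = sp$name, kind = sp$kind,
                                      pars = list(), fit = sp$fit, predict = sp$predict)
    } else {
      grid <- expand.grid(sp$tuning_grid, stringsAsFactors = FALSE)
      for (i in seq_len(nrow(grid))) {
        pars <- as.list(grid[i, , drop = FALSE])
        names(pars) <- names(grid)
        lab <- paste0(sp$name, "_", paste0(names(pars), "=", unlist(pars), collapse = "_"))
        out[[length(out) + 1L]] <- list(name = lab, kind = sp$kind, pars = pars,
                                        fit = sp$fit, predict = sp$predict)
      }
    }
  }
  out
}

# ---- design expansions -----------------------------------------------------

two_way_design <- function(X) {
  p <- ncol(X)
  if (p < 2L) return(X)
  pairs <- utils::combn(p, 2)
  inter <- X[, pairs[1, ], drop = FALSE] * X[, pairs[2, ], drop = FALSE]
  colnames(inter) <- paste0(colnames(X)[pairs[1, ]], ":", colnames(X)[pairs[2, ]])
  cbind(X, inter)
}

spline_design <- function(X, degree = 1, df = 3) {
  cont <- vapply(seq_len(ncol(X)), function(j) length(unique(X[, j])) > 8, logical(1))
  blocks <- list(X[, !cont, drop = FALSE])
  for (j in which(cont)) {
    B <- splines::ns(X[, j], df = df)
    colnames(B) <- paste0(colnames(X)[j], "_ns", seq_len(ncol(B)))
    blocks[[length(blocks) + 1L]] <- B
  }
  D <- do.call(cbind, blocks)
  if (degree >= 2) {
    p <- ncol(X)
    pairs <- utils::combn(p, 2)
    inter <- X[, pairs[1, ], drop = FALSE] * X[, pairs[2, ], drop = FALSE]
    colnames(inter) <- paste0(colnames(X)[pairs[1, ]], "x", colnames(X)[pairs[2, ]])
    D <- cbind(D, inter)
  }
  D
}

# logistic GLM on a raw design matrix; rank deficiencies fall back to 0
glm_design_fit <- function(D, y) {
  fit <- suppressWarnings(stats::glm.fit(cbind(`(Intercept)` = 1, D), y,
                                         family = stats::binomial()))
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  cf
}

glm_design_predict <- function(cf, D) {
  unname(drop(stats::plogis(cbind(1, D) %*% cf)))
}

# ---- fit / predict dispatch ------------------------------------------------

fit_learner <- function(learner, X, y, seed = 1L) {
  X <- as.matrix(X)
  switch(learner$kind,
    glm_main = list(kind = "glm_main", coef = glm_design_fit(X, y)),
    glm_two_way = list(kind = "glm_two_way", coef = glm_design_fit(two_way_design(X), y)),
    mars = {
      deg <- learner$pars$degree %||% 1
      # knots must be frozen at training time for out-of-fold prediction
      cont <- vapply(seq_len(ncol(X)), function(j) length(unique(X[, j])) > 8, logical(1))
      knots <- lapply(which(cont), function(j) {
        b <- splines::ns(X[, j], df = 3)
        list(j = j, knots = attr(b, "knots"), boundary = attr(b, "Boundary.knots"))
      })
      D <- spline_design_frozen(X, knots, deg)
      list(kind = "mars", coef = glm_design_fit(D, y), knots = knots, degree = deg)
    },
    random_forest = {
      p <- ncol(X)
      mtry <- switch(learner$pars$mtry_frac %||% "sqrt",
                     sqrt = max(1L, floor(sqrt(p))),
                     third = max(1L, floor(p / 3)))
      dat <- data.frame(.y = factor(y, levels = c(0, 1)), X)
      fit <- ranger::ranger(dependent.variable.name = ".y", data = dat,
                            num.trees = learner$pars$num_trees %||% 500,
                            mtry = mtry, probability = TRUE,
                            num.threads = 1L, seed = seed,
                            respect.unordered.factors = "order")
      list(kind = "random_forest", fit = fit, cols = colnames(dat)[-1])
    },
    gradient_boosting = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y)
      fit <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                              max_depth = learner$pars$max_depth %||% 3,
                                              eta = learner$pars$eta %||% 0.1,
                                              nthread = 1L, seed = seed),
                                data = dtrain,
                                nrounds = learner$pars$nrounds %||% 100,
                                verbose = 0)
      list(kind = "gradient_boosting", fit = fit)
    },
    custom = list(kind = "custom", fit = learner$fit(X, y), predict = learner$predict)
  )
}

spline_design_frozen <- function(X, knots, degree) {
  cont_idx <- vapply(knots, function(k) k$j, integer(1))
  blocks <- list(X[, setdiff(seq_len(ncol(X)), cont_idx), drop = FALSE])
  for (k in knots) {
    B <- splines::ns(X[, k$j], knots = k$knots, Boundary.knots = k$boundary)
    colnames(B) <- paste0(colnames(X)[k$j], "_ns", seq_len(ncol(B)))
    blocks[[length(blocks) + 1L]] <- B
  }
  D <- do.call(cbind, blocks)
  if (degree >= 2) {
    p <- ncol(X)
    pairs <- utils::combn(p, 2)
    inter <- X[, pairs[1, ], drop = FALSE] * X[, pairs[2, ], drop = FALSE]
    D <- cbind(D, inter)
  }
  D
}

predict_learner <- function(model, X) {
  X <- as.matrix(X)
  switch(model$kind,
    glm_main = glm_design_predict(model$coef, X),
    glm_two_way = glm_design_predict(model$coef, two_way_design(X)),
    mars = glm_design_predict(model$coef,
                              spline_design_frozen(X, model$knots, model$degree)),
    random_forest = {
      pr <- stats::predict(model$fit, data = data.frame(X), num.threads = 1L)$predictions
      pr[, "1"]
    },
    gradient_boosting = stats::predict(model$fit, X),
    custom = model$predict(model$fit, X)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
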