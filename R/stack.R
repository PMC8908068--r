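#' Cross-validated level-one predictions
#'
#' Builds the stacking level-one matrix: rows are observations, columns are
#' (grid-expanded) base learners, and entry (i, j) is learner j's predicted
#' probability for row i from a model trained with row i's fold held out.
#' Fold assignment is deterministic given `seed`. If a training split
#' contains a single outcome class, every learner's prediction for that
#' fold is replaced by the training-split outcome mean (a message is
#' emitted).
#'
#' @param X covariate matrix.
#' @param y binary outcome vector.
#' @param specs list of [learner_spec()] objects.
#' @param v number of folds (>= 2).
#' @param seed integer seed for fold assignment and stochastic learners.
#' @param clip predictions are clipped into `[clip, 1 - clip]`.
#' @return List with `Z` (n x k matrix), `fold_ids`, `learner_names`.
#' @export
cv_level_one <- function(X, y, specs, v = 10L, seed = 1L, clip = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (v < 2L) stopf("v must be >= 2")
  if (n < v) stopf("need at least as many rows as folds")
  if (!all(y %in% c(0, 1))) stopf("y must be binary 0/1")
  learners <- expand_learners(specs)
  k <- length(learners)
  fold_ids <- with_seed(seed, sample(rep(seq_len(v), length.out = n)))
  Z <- matrix(NA_real_, n, k, dimnames = list(NULL, vapply(learners, `[[`, "", "name")))
  for (f in seq_len(v)) {
    test <- fold_ids == f
    ytr <- y[!test]
    if (length(unique(ytr)) < 2L) {
      message(sprintf("fold %d: training split has a single outcome class; using its mean", f))
      Z[test, ] <- mean(ytr)
      next
    }
    Xtr <- X[!test, , drop = FALSE]
    Xte <- X[test, , drop = FALSE]
    for (j in seq_len(k)) {
      m <- fit_learner(learners[[j]], Xtr, ytr, seed = seed + 1000L * f + j)
      Z[test, j] <- predict_learner(m, Xte)
    }
  }
  Z <- clip01(Z, clip)
  list(Z = Z, fold_ids = fold_ids, learner_names = colnames(Z))
}

cv_risk <- function(Z, y, loss = c("log_loss", "squared_error")) {
  loss <- match.arg(loss)
  if (loss == "log_loss") -colMeans(y * log(Z) + (1 - y) * log(1 - Z))
  else colMeans((y - Z)^2)
}

#' Fit a stacked (super learner) model
#'
#' Classical stacked generalization for a binary outcome: base learners are
#' cross-validated to produce the level-one matrix, nonnegative least
#' squares of the outcome on that matrix (normalized to the simplex) gives
#' the meta-weights, and every base learner is then refit on all rows for
#' prediction. A single-learner library short-circuits the cross-validation
#' and gets weight 1.
#'
#' @inheritParams cv_level_one
#' @param loss risk used to rank learners (and break the all-zero NNLS
#'   fallback): `"log_loss"` (default) or `"squared_error"`. The
#'   meta-weights themselves are always the NNLS solution on probabilities.
#' @return Object of class `pp_stack` with `learners` (fitted), `meta_weights`,
#'   `cv_risks`, `v_folds`, `loss`, `seed`, `fold_ids`.
#' @export
fit_stack <- function(X, y, specs = default_learners(), v = 10L,
                      loss = c("log_loss", "squared_error"), seed = 1L) {
  loss <- match.arg(loss)
  X <- as.matrix(X)
  learners <- expand_learners(specs)
  k <- length(learners)
  if (k == 1L) {
    weights <- 1
    risks <- NA_real_
    fold_ids <- rep(1L, nrow(X))
  } else {
    lv1 <- cv_level_one(X, y, specs, v = v, seed = seed)
    risks <- cv_risk(lv1$Z, y, loss)
    weights <- nnls_meta_weights(lv1$Z, y, cv_risks = risks)
    fold_ids <- lv1$fold_ids
  }
  fitted <- vector("list", k)
  for (j in seq_len(k)) {
    if (k > 1L && weights[j] < 1e-12) next  # zero-weight learners never predict
    fitted[[j]] <- fit_learner(learners[[j]], X, y, seed = seed + j)
  }
  structure(list(learners = fitted,
                 learner_defs = learners,
                 learner_names = vapply(learners, `[[`, "", "name"),
                 meta_weights = as.numeric(weights),
                 cv_risks = as.numeric(risks),
                 v_folds = as.integer(v), loss = loss, seed = as.integer(seed),
                 fold_ids = fold_ids, n_cols = ncol(X)),
            class = "pp_stack")
}

#' Predict from a stacked model
#'
#' @param m a [fit_stack()] model.
#' @param X_new covariate matrix with the training column layout.
#' @param clip final predictions are clipped into `[clip, 1 - clip]`.
#' @return Numeric vector of probabilities.
#' @export
predict_stack <- function(m, X_new, clip = 1e-6) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != m$n_cols)
    stopf("X_new has %d columns; the stack was trained on %d", ncol(X_new), m$n_cols)
  pred <- numeric(nrow(X_new))
  for (j in seq_along(m$learners)) {
    if (m$meta_weights[j] < 1e-12 || is.null(m$learners[[j]])) next
    pred <- pred + m$meta_weights[j] * predict_learner(m$learners[[j]], X_new)
  }
  unname(clip01(pred, clip))
}

#' @export
print.pp_stack <- function(x, ...) {
  cat(sprintf("<stack> %d learners, %d-fold CV, loss = %s\n",
              length(x$learner_names), x$v_folds, x$loss))
  df <- data.frame(learner = x$learner_names, weight = round(x$meta_weights, 4),
                   cv_risk = round(x$cv_risks, 5))
  print(df, row.names = FALSE)
  invisible(x)
}
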