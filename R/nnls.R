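#' Nonnegative least squares
#'
#' Lawson-Hanson active-set solver for `min ||y - Z b||^2` subject to
#' `b >= 0`. This is the meta-learner used to combine cross-validated base
#' learner predictions in the stack.
#'
#' @param Z numeric matrix (n x k).
#' @param y numeric response of length n.
#' @param tol convergence tolerance on the dual (gradient) coordinates.
#' @param max_iter safety cap on active-set moves.
#' @return Numeric coefficient vector of length k (not normalized).
#' @export
nnls_solve <- function(Z, y, tol = 1e-8, max_iter = 10L * ncol(Z) + 50L) {
  Z <- as.matrix(Z)
  if (nrow(Z) != length(y)) stopf("rows(Z) must equal length(y)")
  if (ncol(Z) < 1L) stopf("Z needs at least one column")
  if (all(abs(Z) < .Machine$double.eps)) stopf("Z has rank 0")
  k <- ncol(Z)
  beta <- numeric(k)
  passive <- rep(FALSE, k)
  w <- drop(crossprod(Z, y - Z %*% beta))
  iter <- 0L
  while (any(!passive) && max(w[!passive]) > tol) {
    iter <- iter + 1L
    if (iter > max_iter) break
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(k)
      idx <- which(passive)
      fit <- stats::lm.fit(Z[, idx, drop = FALSE], y)
      s[idx] <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      if (all(s[idx] > tol)) { beta <- s; break }
      neg <- idx[s[idx] <= tol]
      alpha <- min(beta[neg] / (beta[neg] - s[neg]))
      beta <- beta + alpha * (s - beta)
      passive[beta <= tol & passive] <- FALSE
      beta[!passive] <- 0
      if (!any(passive)) break
    }
    w <- drop(crossprod(Z, y - Z %*% beta))
  }
  beta
}

#' Normalized NNLS meta-weights
#'
#' Solves the nonnegative least squares problem of the stack's level-one
#' predictions against the outcome and normalizes the solution to sum to 1
#' (a convex combination of learners). If the NNLS solution is identically
#' zero, weight 1 falls back to the learner with the lowest cross-validated
#' risk (a message is emitted).
#'
#' @param Z level-one prediction matrix, one column per learner.
#' @param y outcome vector.
#' @param cv_risks optional per-learner cross-validated risks used only for
#'   the all-zero fallback; defaults to column squared error.
#' @param tol NNLS tolerance.
#' @return Weight vector on the simplex (nonnegative, sums to 1).
#' @export
nnls_meta_weights <- function(Z, y, cv_risks = NULL, tol = 1e-8) {
  Z <- as.matrix(Z)
  beta <- nnls_solve(Z, y, tol = tol)
  if (sum(beta) <= 0) {
    if (is.null(cv_risks)) cv_risks <- colMeans((y - Z)^2)
    message("NNLS returned an all-zero solution; falling back to the lowest-risk learner")
    beta <- numeric(ncol(Z))
    beta[which.min(cv_risks)] <- 1
    return(beta)
  }
  beta / sum(beta)
}
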