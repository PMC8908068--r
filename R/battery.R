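# keep the covariate attribute when subsetting analytic rows
subset_rows <- function(rows, keep) {
  out <- rows[keep, , drop = FALSE]
  attr(out, "covariates") <- attr(rows, "covariates")
  attr(out, "protocol") <- attr(rows, "protocol")
  out
}

#' Run the full estimator battery
#'
#' For each requested estimand, runs every requested method and stacks the
#' results into one report shaped like a published effect table. The ITT
#' estimand contrasts randomized arms on the full sample; the per-protocol
#' estimand restricts to the adherent subset under protocol `p` and
#' contrasts randomized arms adjusted for baseline covariates. AIPW and
#' TMLE share one set of cross-fit stacked nuisances per estimand.
#'
#' Setting `adjust_postrandomization = TRUE` appends the dichotomized
#' bleeding and nausea flags to the adjustment set — the variant that
#' conditions on postrandomization covariates, which can itself introduce
#' bias and is reported only for comparison.
#'
#' @param trial a [pp_trial()].
#' @param p a [protocol()].
#' @param methods subset of `c("aipw", "tmle", "gcomp", "ipw", "unadjusted")`.
#' @param estimands subset of `c("itt", "per_protocol")`.
#' @param specs learner library for the AIPW/TMLE nuisance stacks.
#' @param k cross-fitting folds.
#' @param v stack-internal cross-validation folds.
#' @param truncation_bounds propensity truncation.
#' @param boot bootstrap replicates for g-computation.
#' @param seed integer seed.
#' @param adjust_postrandomization include bleeding/nausea flags in the
#'   adjustment set.
#' @return A `pp_estimates` data frame (methods x scales x estimands), with
#'   attributes `"nuisance_log"` (truncation counts and stack weights) and
#'   `"protocol"`.
#' @export
estimate_battery <- function(trial, p = protocol(),
                             methods = c("aipw", "tmle", "gcomp", "ipw", "unadjusted"),
                             estimands = c("itt", "per_protocol"),
                             specs = glm_learners(), k = 5L, v = 5L,
                             truncation_bounds = c(0.025, 0.975),
                             boot = 1000L, seed = 1L,
                             adjust_postrandomization = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  estimands <- match.arg(estimands, several.ok = TRUE)
  an <- build_analytic(trial, p)
  extra <- if (adjust_postrandomization) c("bleeding_flag", "nausea_flag") else character(0)
  out <- list(); log <- list()
  for (est in estimands) {
    rows <- if (est == "per_protocol") subset_rows(an, an$C == 1L) else an
    nu <- NULL
    if (any(c("aipw", "tmle") %in% methods)) {
      nu <- cross_fit_nuisances(rows, specs = specs, k = k, v = v,
                                truncation_bounds = truncation_bounds,
                                seed = seed + match(est, c("itt", "per_protocol")),
                                extra_covariates = extra)
      log[[est]] <- list(n_truncated = nu$n_truncated,
                         propensity_weights = nu$propensity_weights,
                         outcome_weights = nu$outcome_weights)
    }
    for (m in methods) {
      out[[paste(est, m)]] <- switch(m,
        aipw = aipw(rows, nu, estimand = est),
        tmle = tmle(rows, nu, estimand = est),
        gcomp = gcomp(rows, estimand = est, boot = boot, seed = seed + 17L,
                      extra_covariates = extra),
        ipw = ipw(rows, estimand = est, truncation_bounds = truncation_bounds,
                  extra_covariates = extra),
        unadjusted = unadjusted(rows, estimand = est))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("pp_estimates", "data.frame")
  attr(res, "nuisance_log") <- log
  attr(res, "protocol") <- p
  res
}

#' Adherence-threshold sensitivity sweep
#'
#' Re-derives adherence and re-estimates the per-protocol effect under each
#' protocol in the grid (default: d in {4,5,6} crossed with f in
#' {0.60, 0.70, 0.80}), reporting the adherent count and the cross-fit AIPW
#' risk difference and risk ratio.
#'
#' @inheritParams estimate_battery
#' @param protocols list of [protocol()] objects.
#' @return Data frame with one row per protocol: `d`, `f`, `n_adherent`,
#'   `rd`, `rd_ci_lower`, `rd_ci_upper`, `rr`, `rr_ci_lower`,
#'   `rr_ci_upper`.
#' @export
protocol_sweep <- function(trial, protocols = protocol_grid(),
                           specs = glm_learners(), k = 5L, v = 5L,
                           truncation_bounds = c(0.025, 0.975), seed = 1L) {
  res <- lapply(seq_along(protocols), function(i) {
    p <- protocols[[i]]
    an <- build_analytic(trial, p)
    rows <- subset_rows(an, an$C == 1L)
    nu <- cross_fit_nuisances(rows, specs = specs, k = k, v = v,
                              truncation_bounds = truncation_bounds, seed = seed + i)
    es <- aipw(rows, nu)
    data.frame(d = p$d, f = p$f, n_adherent = sum(an$C),
               rd = es$point[1], rd_ci_lower = es$ci_lower[1], rd_ci_upper = es$ci_upper[1],
               rr = es$point[2], rr_ci_lower = es$ci_lower[2], rr_ci_upper = es$ci_upper[2])
  })
  do.call(rbind, res)
}
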