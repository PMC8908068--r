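#' Analysis configuration
#'
#' Validated configuration for [run_analysis()]. Unknown keys are rejected
#' so config-file typos fail before any computation.
#'
#' @param dgp `NULL`, or a [dgp_params()] object / named list of its
#'   arguments: simulate the input trial instead of reading it.
#' @param input_stem path stem of a CSV pair written by
#'   [write_trial_csv()]; required when `dgp` is `NULL`.
#' @param protocol_d,protocol_f the primary protocol.
#' @param run_sweep run the 3 x 3 adherence-threshold sweep.
#' @param methods estimators for [estimate_battery()].
#' @param estimands `"itt"`, `"per_protocol"` or both.
#' @param learners `"glm"` (main-effects GLM nuisances) or `"default"`
#'   (the five-family stack).
#' @param k_folds cross-fitting folds; `v_folds` stack-internal CV folds.
#' @param truncation_lower,truncation_upper propensity truncation bounds.
#' @param boot g-computation bootstrap replicates.
#' @param adjust_postrandomization append bleeding/nausea flags to the
#'   adjustment set.
#' @param seed integer master seed.
#' @param output_dir directory for `table1.csv`, `estimates.json`,
#'   `sweep.csv` and `run.log`.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(dgp = NULL, input_stem = NULL,
                            protocol_d = 5L, protocol_f = 0.8,
                            run_sweep = FALSE,
                            methods = c("aipw", "tmle", "gcomp", "ipw", "unadjusted"),
                            estimands = c("itt", "per_protocol"),
                            learners = c("glm", "default"),
                            k_folds = 5L, v_folds = 5L,
                            truncation_lower = 0.025, truncation_upper = 0.975,
                            boot = 1000L, adjust_postrandomization = FALSE,
                            seed = 1L, output_dir = "pp-analysis-output") {
  learners <- match.arg(learners)
  if (is.null(dgp) && is.null(input_stem))
    stopf("config needs either `dgp` (simulate) or `input_stem` (read CSVs)")
  if (!is.null(dgp) && !inherits(dgp, "dgp_params")) {
    if (!is.list(dgp)) stopf("`dgp` must be a dgp_params object or a named list")
    dgp <- do.call(dgp_params, dgp)
  }
  if (truncation_lower <= 0 || truncation_upper >= 1 || truncation_lower >= truncation_upper)
    stopf("truncation bounds must satisfy 0 < lower < upper < 1")
  cfg <- list(dgp = dgp, input_stem = input_stem,
              protocol_d = as.integer(protocol_d), protocol_f = protocol_f,
              run_sweep = isTRUE(run_sweep), methods = methods,
              estimands = estimands, learners = learners,
              k_folds = as.integer(k_folds), v_folds = as.integer(v_folds),
              truncation_lower = truncation_lower, truncation_upper = truncation_upper,
              boot = as.integer(boot),
              adjust_postrandomization = isTRUE(adjust_postrandomization),
              seed = as.integer(seed), output_dir = output_dir)
  protocol(cfg$protocol_d, cfg$protocol_f)  # validates
  structure(cfg, class = "analysis_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' Keys mirror the arguments of [analysis_config()]; unknown keys are
#' rejected with a field-level message.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return An [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stopf("unknown config key(s): %s (known keys: %s)",
          paste(unknown, collapse = ", "), paste(known, collapse = ", "))
  if (!is.null(raw$dgp))
    for (nm in c("covariate_prevalences", "exercise_probs", "prior_losses_probs",
                 "prior_live_births_probs", "adherence_coefs", "side_effect_coefs",
                 "outcome_coefs"))
      if (!is.null(raw$dgp[[nm]])) raw$dgp[[nm]] <- unlist(raw$dgp[[nm]])
  do.call(analysis_config, raw)
}

#' Run the configured analysis end to end
#'
#' Executes: simulate (or read) the trial, derive adherence under the
#' primary protocol, build the descriptive table, run the estimator
#' battery, optionally sweep the 3 x 3 protocol grid; then writes
#' `table1.csv`, `estimates.json`, optionally `sweep.csv`, and `run.log`
#' to the output directory. All results are computed before anything is
#' written, so a failure never leaves partial outputs. Risk differences
#' are reported both as proportions and per 100 women. Byte-identical
#' outputs for identical configurations.
#'
#' @param config an [analysis_config()] (or a path to a config file).
#' @return Invisibly, a list with `trial`, `table_one`, `estimates`,
#'   `sweep` (or `NULL`) and the output paths.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  if (!inherits(config, "analysis_config")) stopf("`config` must be an analysis_config")
  log_lines <- c(sprintf("perprotocol run, seed = %d", config$seed),
                 sprintf("protocol: >= %d of 7 pill-days for >= %d%% of person-weeks",
                         config$protocol_d, round(100 * config$protocol_f)))
  trial <- if (!is.null(config$dgp)) {
    log_lines <- c(log_lines, sprintf("simulated trial: n = %d, dgp seed = %d",
                                      config$dgp$n_participants, config$seed))
    simulate_trial(config$dgp, seed = config$seed)
  } else {
    log_lines <- c(log_lines, sprintf("trial read from CSVs: %s", config$input_stem))
    read_trial_csv(config$input_stem)
  }
  p <- protocol(config$protocol_d, config$protocol_f)
  an <- build_analytic(trial, p)
  t1 <- table_one(an)
  specs <- if (config$learners == "glm") glm_learners() else default_learners()
  trunc <- c(config$truncation_lower, config$truncation_upper)
  msgs <- character(0)
  est <- withCallingHandlers(
    estimate_battery(trial, p, methods = config$methods,
                     estimands = config$estimands, specs = specs,
                     k = config$k_folds, v = config$v_folds,
                     truncation_bounds = trunc, boot = config$boot,
                     seed = config$seed,
                     adjust_postrandomization = config$adjust_postrandomization),
    message = function(m) { msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage") })
  sweep <- NULL
  if (config$run_sweep) {
    sweep <- withCallingHandlers(
      protocol_sweep(trial, specs = specs, k = config$k_folds, v = config$v_folds,
                     truncation_bounds = trunc, seed = config$seed + 1000L),
      message = function(m) { msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage") })
  }
  log_lines <- c(log_lines, sprintf("adherent: %d of %d (%.1f%%)", sum(an$C), nrow(an),
                                    100 * mean(an$C)),
                 sub("\n$", "", msgs))
  nl <- attr(est, "nuisance_log")
  for (nm in names(nl)) {
    log_lines <- c(log_lines,
                   sprintf("[%s] propensity truncation events: %d", nm, nl[[nm]]$n_truncated),
                   sprintf("[%s] mean propensity stack weights: %s", nm,
                           paste(round(colMeans(nl[[nm]]$propensity_weights), 3), collapse = " ")),
                   sprintf("[%s] mean outcome stack weights: %s", nm,
                           paste(round(colMeans(nl[[nm]]$outcome_weights), 3), collapse = " ")))
  }

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(table1 = file.path(config$output_dir, "table1.csv"),
                estimates = file.path(config$output_dir, "estimates.json"),
                sweep = if (config$run_sweep) file.path(config$output_dir, "sweep.csv"),
                log = file.path(config$output_dir, "run.log"))
  write_table_one(t1, path_csv = paths$table1)
  est_out <- as.data.frame(est)
  est_out$point_per_100 <- ifelse(est_out$scale == "risk_difference",
                                  100 * est_out$point, NA_real_)
  jsonlite::write_json(list(package_version = as.character(utils::packageVersion("perprotocol")),
                            seed = config$seed,
                            protocol = list(d = p$d, f = p$f),
                            estimates = est_out),
                       paths$estimates, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(sweep)) utils::write.csv(sweep, paths$sweep, row.names = FALSE)
  writeLines(log_lines, paths$log)
  invisible(list(trial = trial, table_one = t1, estimates = est, sweep = sweep,
                 paths = paths))
}
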