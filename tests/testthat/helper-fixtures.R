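# shared fixtures, all built in code

# minimal single-participant history for the per-woman derivation functions
make_history <- function(pill_days, bleeding_days = rep(0L, length(pill_days)),
                         nausea_days = rep(0L, length(pill_days)),
                         pregnancy_week = NA_integer_, id = 1L) {
  list(id = id, arm = "aspirin",
       weeks = data.frame(id = id, week = seq_along(pill_days),
                          pill_days = pill_days, bleeding_days = bleeding_days,
                          nausea_days = nausea_days),
       outcome_hcg = as.integer(!is.na(pregnancy_week)),
       pregnancy_week = pregnancy_week)
}

# small default-shaped trial, memoized per (n, seed)
local({
  cache <- new.env(parent = emptyenv())
  sim_trial_cached <<- function(n = 600, seed = 101) {
    key <- paste0("t", n, "_", seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- simulate_trial(dgp_params(n_participants = n), seed = seed)
    cache[[key]]
  }
})

# high-precision oracle truth for the default generator, computed once
local({
  cache <- new.env(parent = emptyenv())
  default_truth <<- function() {
    if (is.null(cache$te))
      cache$te <- true_estimands(dgp_params(), protocol(5, 0.8), n_mc = 2e5, seed = 99)
    cache$te
  }
})

# published baseline-table counts shipped with the package
table1_counts <- function() {
  path <- system.file("extdata", "eager_table1_counts.csv", package = "perprotocol")
  read.csv(path, stringsAsFactors = FALSE)
}

table1_matrix <- function(counts, var) {
  sub <- counts[counts$variable == var, ]
  t(as.matrix(sub[, c("nonadherent", "adherent")]))
}

# learner that ignores the data and predicts a fixed function of X
oracle_learner <- function(fun, name = "oracle") {
  learner_spec(name, kind = "custom",
               fit = function(X, y) fun,
               predict = function(object, X) object(X))
}

# learner that predicts its training-set outcome mean everywhere
mean_learner <- function() {
  learner_spec("const_mean", kind = "custom",
               fit = function(X, y) mean(y),
               predict = function(object, X) rep(object, nrow(X)))
}

# constant-covariate analytic rows (forces intercept-only nuisance models)
constant_covariate_rows <- function(A, Y) {
  out <- data.frame(A = A, Y = Y, w0 = 0)
  attr(out, "covariates") <- "w0"
  out
}
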