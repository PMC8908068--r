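#' Pearson chi-square test for a contingency table
#'
#' Uncorrected Pearson statistic `sum((O - E)^2 / E)` with expected counts
#' from the product of the margins, df = (r-1)(c-1), upper-tail chi-square
#' p-value. The Yates continuity correction is off by default so that
#' statistics computed from published 2 x 2 counts match the uncorrected
#' values; set `correct = TRUE` for the corrected variant.
#'
#' @param counts matrix of nonnegative counts (at least 2 x 2), or a
#'   `table`.
#' @param correct apply the continuity correction (2 x 2 only).
#' @return List of class `pp_test` with `statistic`, `df`, `p_value`,
#'   `method`.
#' @export
pearson_chi_square <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L) stopf("table must be at least 2 x 2")
  if (any(counts < 0)) stopf("counts must be nonnegative")
  if (sum(counts) <= 0) stopf("table has a zero grand total")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stopf("degenerate table: a zero row or column margin")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 method = if (correct) "Pearson chi-square (continuity-corrected)"
                          else "Pearson chi-square"),
            class = "pp_test")
}

#' Kruskal-Wallis rank-sum test
#'
#' Standard Kruskal-Wallis statistic with the tie correction and the
#' chi-square approximation for the p-value, df = number of groups - 1.
#'
#' @param groups list of two or more non-empty numeric vectors.
#' @return List of class `pp_test` (see [pearson_chi_square()]).
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stopf("need at least two groups")
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stopf("every group must be non-empty")
  if (sum(sizes) < 3L) stopf("need at least 3 observations in total")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  if (length(unique(x)) == 1L)  # fully tied data carry no rank information
    return(structure(list(statistic = 0, df = length(groups) - 1L, p_value = 1,
                          method = "Kruskal-Wallis"), class = "pp_test"))
  ht <- stats::kruskal.test(x, g)
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = unname(ht$p.value), method = "Kruskal-Wallis"),
            class = "pp_test")
}

#' @export
print.pp_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.3f, df = %d, p = %.4g\n",
              x$method, x$statistic, x$df, x$p_value))
  invisible(x)
}

table_one_variables <- function() {
  list(categorical = c("A", "Y", "white", "hs_education", "married", "employed",
                       "income_ge_40k", "exercise", "prior_losses",
                       "prior_live_births", "alcohol_past_year", "smoked_past_year",
                       "bleeding_flag", "nausea_flag"),
       continuous = c("age", "months_trying", "bmi", "hscrp"))
}

#' Baseline-characteristics table by adherence status
#'
#' Builds the standard "Table 1": for each categorical variable, counts and
#' percentages by adherence group with an uncorrected Pearson chi-square
#' test; for each continuous variable, median (IQR) by group with a
#' Kruskal-Wallis test. Randomized arm, outcome and the postrandomization
#' side-effect flags are tabulated alongside the baseline covariates.
#'
#' @param rows analytic data frame from [build_analytic()]; categorical
#'   covariates are recovered from the indicator encoding.
#' @param baseline optional raw baseline data frame (same ids) to tabulate
#'   the original categorical levels; defaults to reconstructing them from
#'   `rows`.
#' @return List of class `pp_table_one` with a `variables` data frame (one
#'   row per variable x level), a `tests` data frame (one row per variable),
#'   and `group_n`.
#' @export
table_one <- function(rows, baseline = NULL) {
  if (length(unique(rows$C)) < 2L)
    stopf("adherence column is constant; need both adherence groups")
  df <- rows
  df$exercise <- ifelse(rows$exercise_high == 1, "high",
                        ifelse(rows$exercise_moderate == 1, "moderate", "low"))
  df$prior_losses <- ifelse(rows$prior_losses_2 == 1, 2L, 1L)
  df$prior_live_births <- with(rows, ifelse(prior_live_births_3 == 1, 3L,
                                     ifelse(prior_live_births_2 == 1, 2L,
                                     ifelse(prior_live_births_1 == 1, 1L, 0L))))
  vars <- table_one_variables()
  grp <- factor(df$C, levels = c(0, 1), labels = c("nonadherent", "adherent"))
  var_rows <- list(); test_rows <- list()
  for (v in vars$categorical) {
    tab <- table(factor(df[[v]]), grp)
    tst <- pearson_chi_square(t(tab))
    pct <- sweep(tab, 2, colSums(tab), "/") * 100
    var_rows[[v]] <- data.frame(variable = v, level = rownames(tab),
                                n_nonadherent = as.integer(tab[, 1]),
                                pct_nonadherent = round(pct[, 1], 1),
                                n_adherent = as.integer(tab[, 2]),
                                pct_adherent = round(pct[, 2], 1),
                                row.names = NULL)
    test_rows[[v]] <- data.frame(variable = v, test = "chi-square",
                                 statistic = tst$statistic, df = tst$df,
                                 p_value = tst$p_value)
  }
  for (v in vars$continuous) {
    sp <- split(df[[v]], grp)
    tst <- kruskal_wallis(sp)
    q <- vapply(sp, function(x) stats::quantile(x, c(0.25, 0.5, 0.75)), numeric(3))
    var_rows[[v]] <- data.frame(variable = v, level = "median (IQR)",
                                n_nonadherent = NA_integer_,
                                pct_nonadherent = NA_real_,
                                n_adherent = NA_integer_, pct_adherent = NA_real_,
                                median_nonadherent = q[2, 1], q1_nonadherent = q[1, 1],
                                q3_nonadherent = q[3, 1], median_adherent = q[2, 2],
                                q1_adherent = q[1, 2], q3_adherent = q[3, 2],
                                row.names = NULL)
    test_rows[[v]] <- data.frame(variable = v, test = "kruskal-wallis",
                                 statistic = tst$statistic, df = tst$df,
                                 p_value = tst$p_value)
  }
  cat_block <- do.call(rbind, var_rows[vars$categorical])
  cont_block <- do.call(rbind, var_rows[vars$continuous])
  for (cc in setdiff(names(cont_block), names(cat_block))) cat_block[[cc]] <- NA_real_
  structure(list(variables = rbind(cat_block, cont_block),
                 tests = do.call(rbind, c(test_rows, list(make.row.names = FALSE))),
                 group_n = table(grp)),
            class = "pp_table_one")
}

#' @export
print.pp_table_one <- function(x, ...) {
  cat(sprintf("<table one> n = %d nonadherent / %d adherent\n",
              x$group_n[[1]], x$group_n[[2]]))
  print(x$tests, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Serialize a table-one report
#' @param x a `pp_table_one`.
#' @param path_csv,path_json output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_table_one <- function(x, path_csv = NULL, path_json = NULL) {
  if (!is.null(path_csv)) {
    merged <- merge(x$variables, x$tests, by = "variable", all.x = TRUE, sort = FALSE)
    utils::write.csv(merged, path_csv, row.names = FALSE)
  }
  if (!is.null(path_json))
    jsonlite::write_json(list(group_n = as.list(x$group_n),
                              variables = x$variables, tests = x$tests),
                         path_json, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(csv = path_csv, json = path_json))
}
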