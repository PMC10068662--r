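# Datamarts: pivot long-form feature rows into wide one-row-per-unit tables
# and carve cohort data tables out of them with inclusion predicates.

#' Pivot a long-form feature table into a wide datamart table
#'
#' One row per statistical unit, one column per feature. Missing
#' (unit, feature) combinations become `NA`; duplicated combinations are an
#' error (they would silently overwrite data).
#'
#' @param long_rows data.table with a key column, a `feature` column and a
#'   `value` column (e.g. from [extract_features()]).
#' @param unit name of the key column (default `"intervention_id"`).
#' @return a `wide_table`: a data.table keyed by `unit`, with attributes
#'   `unit`, `features` (source feature names) and `built_at`.
#' @export
#' @examples
#' long <- data.frame(intervention_id = c("I1", "I1", "I2"),
#'                    feature = c("a", "b", "a"), value = c(1, 2, 3))
#' pivot_features(long)
pivot_features <- function(long_rows, unit = "intervention_id") {
  long <- as.data.table(long_rows)
  assert_that(all(c(unit, "feature", "value") %in% names(long)),
              "long rows need columns %s, feature, value", u = unit,
              class = "pivot_error")
  dup <- long[, .N, by = c(unit, "feature")][N > 1]
  if (nrow(dup) > 0)
    stop_pdw("duplicate (unit, feature) pairs: %s", "pivot_error",
             paste(utils::head(paste0(dup[[unit]], "/", dup$feature), 10),
                   collapse = ", "))
  wide <- dcast(long, stats::as.formula(paste(unit, "~ feature")),
                value.var = "value")
  setorderv(wide, unit)
  setattr(wide, "unit", unit)
  setattr(wide, "features", sort(unique(long$feature)))
  setattr(wide, "built_at", fmt_ts(as_utc(Sys.time())))
  setattr(wide, "class", c("wide_table", class(wide)))
  wide
}

#' Unpivot a wide datamart table back to long form
#'
#' Inverse of [pivot_features()] up to row order: `NA` cells are dropped, so
#' unpivoting a pivoted table reproduces the long-form input as a set.
#'
#' @param wide a `wide_table`.
#' @return data.table with the key column, `feature` and `value`.
#' @export
unpivot_features <- function(wide) {
  unit <- attr(wide, "unit") %||% names(wide)[1]
  long <- melt(as.data.table(wide), id.vars = unit, variable.name = "feature",
               value.name = "value", variable.factor = FALSE)
  long <- long[!is.na(value)]
  setorderv(long, c(unit, "feature"))
  long[]
}

#' Cohort specification and extraction
#'
#' A cohort is the subset of a wide table whose rows satisfy every inclusion
#' predicate, restricted to the selected variables. Predicates are R
#' expressions over column names (as strings), evaluated with three-valued
#' logic: a predicate that evaluates to `NA` for a row (a null cell)
#' excludes that row — the safe behavior for inclusion criteria. Output rows
#' are ordered by key.
#'
#' @param unit key column name.
#' @param include character vector of predicate expressions, e.g.
#'   `"age >= 18"`; empty means include everyone.
#' @param variables columns to keep (the key is always kept); `NULL` keeps
#'   all.
#' @return `cohort_spec()`: a `cohort_spec`; `build_cohort()`: a data.table.
#' @export
#' @examples
#' wt <- pivot_features(data.frame(intervention_id = c("I1", "I2"),
#'                                 feature = "age", value = c(17, 44)))
#' build_cohort(wt, cohort_spec(include = "age >= 18"))
cohort_spec <- function(unit = "intervention_id", include = character(),
                        variables = NULL) {
  structure(list(unit = unit, include = include, variables = variables),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @param wide a `wide_table` (or data.frame) to filter.
#' @param spec a `cohort_spec`.
#' @export
build_cohort <- function(wide, spec) {
  dt <- as.data.table(wide)
  unit <- spec$unit
  assert_that(unit %in% names(dt), "key column '%s' absent from wide table",
              class = "spec_error", u = unit)
  keep <- rep(TRUE, nrow(dt))
  for (pred in spec$include) {
    expr <- parse(text = pred)[[1]]
    refs <- setdiff(all.vars(expr), names(dt))
    assert_that(length(refs) == 0,
                "predicate '%s' references missing column(s): %s",
                class = "spec_error", p = pred,
                r = paste(refs, collapse = ", "))
    val <- eval(expr, envir = dt, enclos = parent.frame())
    keep <- keep & !is.na(val) & val
  }
  cols <- if (is.null(spec$variables)) names(dt)
          else union(unit, spec$variables)
  missing_cols <- setdiff(cols, names(dt))
  assert_that(length(missing_cols) == 0,
              "selected variable(s) not in wide table: %s",
              class = "spec_error", v = paste(missing_cols, collapse = ", "))
  out <- dt[keep, cols, with = FALSE]
  setorderv(out, unit)
  out[]
}

#' Percentage of flagged units in a cohort
#'
#' The standard cohort-description statistic, e.g. "240 of 387 patients
#' (62.0%) had myocardial injury after non-cardiac surgery": 100 x
#' n_flagged / n_total, rounded half-up to one decimal.
#'
#' @param n_flagged,n_total non-negative counts, `n_flagged <= n_total`,
#'   `n_total > 0`.
#' @return percentage, one decimal.
#' @export
#' @examples
#' cohort_summary(240, 387)  # 62.0
#' cohort_summary(166, 387)  # 42.9
cohort_summary <- function(n_flagged, n_total) {
  assert_that(length(n_total) == length(n_flagged),
              "n_flagged and n_total must have equal length")
  assert_that(all(n_total > 0), "n_total must be positive",
              class = "undefined_rate")
  assert_that(all(n_flagged >= 0 & n_flagged <= n_total),
              "need 0 <= n_flagged <= n_total")
  round_half_up(100 * n_flagged / n_total, 1)
}
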