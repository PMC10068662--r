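# Four-axis data quality: completeness (required fields and events),
# correctness (values and vocabularies within expectation), concordance
# (agreement across sources, e.g. the operating-room date falls inside the
# linked hospital stay), plausibility (internally possible dates). Checks
# run against a staged source bundle or against the loaded warehouse and
# never mutate either.

#' Declare a data-quality check
#'
#' A check evaluates a predicate over the rows of one table and reports the
#' keys that fail. `fn` receives the full table set (a named list of
#' data.tables) and must return a data.table (`key`, `pass`).
#'
#' @param check_id short unique id.
#' @param axis one of `"completeness"`, `"correctness"`, `"concordance"`,
#'   `"plausibility"`.
#' @param scope name of the table the check evaluates.
#' @param fn function(tables) -> data.table(`row_key`, `pass`).
#' @return a `dq_check`.
#' @export
dq_check <- function(check_id, axis, scope, fn) {
  assert_that(axis %in% c("completeness", "correctness", "concordance",
                          "plausibility"),
              "unknown axis '%s'", class = "config_error", a = axis)
  structure(list(check_id = check_id, axis = axis, scope = scope, fn = fn),
            class = "dq_check")
}

# normalize either input shape (staging bundle or warehouse) to a common
# named list of tables
dq_tables <- function(x) {
  if (inherits(x, "warehouse")) {
    tb <- x$tables
    list(interventions = tb$intervention, measurements = tb$measurement,
         events = tb$event_record, stays = tb$hospital_stay,
         unit_stays = tb$unit_stay, diagnoses = tb$diagnosis,
         procedures = tb$procedure, biology = tb$biology, deaths = tb$death,
         patients = tb$patient)
  } else if (inherits(x, "staging")) {
    x$tables
  } else if (inherits(x, "source_bundle_set")) {
    x$bundle
  } else {
    x
  }
}

#' Built-in data-quality check suite
#'
#' Completeness: every intervention documents the required anesthesia and
#' surgery step events; every measurement has a value. Correctness:
#' measurement values inside the configured plausibility range, drug doses
#' in the standard unit, signal codes and event labels drawn from the
#' canonical vocabulary (source-side checks, before cleaning). Concordance:
#' the operating-room date of each intervention is contained in a hospital
#' stay of the same patient. Plausibility: discharge on or after admission;
#' death on or after the last discharge; room exit after room entry.
#'
#' @param config an [etl_config()].
#' @param source_checks include the vocabulary checks that only make sense
#'   before cleaning (set `FALSE` when running against the warehouse).
#' @return list of [dq_check()]s.
#' @export
default_dq_suite <- function(config = etl_config(), source_checks = TRUE) {
  req <- config$required_events
  canon_events <- unique(c(step_event_labels(), drug_catalog()$drug_label,
                           config$synonyms_events$canonical))
  canon_signals <- config$ranges$signal_code

  suite <- list(
    dq_check("required_events", "completeness", "interventions",
             function(tb) {
               ev <- tb$events[, .(n_req = uniqueN(
                 intersect(event_label, req))), by = intervention_id]
               ids <- tb$interventions$intervention_id
               n_req <- ev$n_req[match(ids, ev$intervention_id)]
               data.table(row_key = ids,
                          pass = !is.na(n_req) & n_req == length(req))
             }),
    dq_check("measurement_value_present", "completeness", "measurements",
             function(tb) data.table(row_key = tb$measurements$measurement_id,
                                     pass = !is.na(tb$measurements$value))),
    dq_check("measurement_attributable", "completeness", "measurements",
             function(tb) data.table(
               row_key = tb$measurements$measurement_id,
               pass = !is.na(tb$measurements$intervention_id))),
    dq_check("measurement_in_range", "correctness", "measurements",
             function(tb) {
               ms <- tb$measurements
               rt <- config$ranges
               m <- match(ms$signal_code, rt$signal_code)
               pass <- !is.na(m) & !is.na(ms$value) &
                 ms$value >= rt$lo[m] & ms$value <= rt$hi[m]
               # unknown codes are judged by the vocabulary check, not here
               pass[is.na(m)] <- TRUE
               data.table(row_key = ms$measurement_id, pass = pass)
             }),
    dq_check("drug_unit_standard", "correctness", "events",
             function(tb) {
               dr <- tb$events[kind == "drug"]
               data.table(row_key = dr$event_id,
                          pass = dr$dose_unit == config$drug_range$unit)
             }),
    dq_check("or_date_within_stay", "concordance", "interventions",
             function(tb) {
               iv <- tb$interventions
               lk <- link_records(iv, tb$stays)
               data.table(row_key = iv$intervention_id,
                          pass = iv$intervention_id %in% lk$links$intervention_id)
             }),
    dq_check("discharge_after_admission", "plausibility", "stays",
             function(tb) data.table(
               row_key = tb$stays$stay_id,
               pass = tb$stays$discharge_date >= tb$stays$admission_date)),
    dq_check("death_after_discharge", "plausibility", "deaths",
             function(tb) {
               if (nrow(tb$deaths) == 0)
                 return(data.table(row_key = character(), pass = logical()))
               last_dis <- tb$stays[, .(last = max(discharge_date)),
                                    by = patient_id]
               m <- match(tb$deaths$patient_id, last_dis$patient_id)
               data.table(row_key = tb$deaths$patient_id,
                          pass = is.na(m) | tb$deaths$death_date >= last_dis$last[m])
             }),
    dq_check("room_exit_after_entry", "plausibility", "interventions",
             function(tb) data.table(
               row_key = tb$interventions$intervention_id,
               pass = tb$interventions$room_exit_ts > tb$interventions$room_entry_ts))
  )
  if (source_checks) {
    suite <- c(suite, list(
      dq_check("signal_code_canonical", "correctness", "measurements",
               function(tb) data.table(
                 row_key = tb$measurements$measurement_id,
                 pass = tb$measurements$signal_code %in% canon_signals)),
      dq_check("event_label_canonical", "correctness", "events",
               function(tb) data.table(
                 row_key = tb$events$event_id,
                 pass = normalize_label(tb$events$event_label) %in%
                   normalize_label(c(canon_events,
                                     config$synonyms_events$variant))))
    ))
  }
  suite
}

#' Run a data-quality check suite
#'
#' Evaluates every check against a staged bundle or a loaded warehouse and
#' returns a deterministic report; the input is never mutated. Failure keys
#' are sampled (first `max_keys` in key order) to keep reports readable.
#'
#' @param x a `source_bundle_set`, `staging`, `warehouse`, or bare table
#'   list.
#' @param suite list of [dq_check()]s (default [default_dq_suite()]).
#' @param max_keys cap on reported failure keys per check.
#' @return a `dq_report`: data.table with `check_id`, `axis`, `scope`,
#'   `n_evaluated`, `n_failed`, `pass_rate`, `failed_keys`.
#' @export
run_dq <- function(x, suite = default_dq_suite(), max_keys = 50L) {
  assert_that(length(suite) > 0, "empty check suite", class = "config_error")
  tb <- dq_tables(x)
  rows <- lapply(suite, function(chk) {
    assert_that(chk$scope %in% names(tb),
                "check '%s' references missing table '%s'",
                class = "config_error", id = chk$check_id, s = chk$scope)
    res <- chk$fn(tb)
    failed <- sort(res$row_key[!res$pass])
    data.table(check_id = chk$check_id, axis = chk$axis, scope = chk$scope,
               n_evaluated = nrow(res), n_failed = length(failed),
               pass_rate = if (nrow(res) == 0) 1
                           else 1 - length(failed) / nrow(res),
               failed_keys = paste(utils::head(failed, max_keys),
                                   collapse = ","))
  })
  out <- rbindlist(rows)
  setattr(out, "class", c("dq_report", class(out)))
  out
}

#' Persist a data-quality report into the warehouse history
#'
#' Appends the report to the `dq_result` table under the next run id, so
#' indicator trends can be followed across loads.
#'
#' @param wh a `warehouse`.
#' @param report a `dq_report`.
#' @return the updated `warehouse`.
#' @export
record_dq <- function(wh, report) {
  run <- if (nrow(wh$tables$dq_result) == 0) 1L
         else max(wh$tables$dq_result$dq_run_id) + 1L
  add <- as.data.table(report)[, .(dq_run_id = run, check_id, axis, scope,
                                   n_evaluated = as.integer(n_evaluated),
                                   n_failed = as.integer(n_failed),
                                   pass_rate, failed_keys)]
  wh$tables$dq_result <- rbind(wh$tables$dq_result, add)
  wh
}

#' @export
print.dq_report <- function(x, ...) {
  cat("<dq_report>\n")
  print(as.data.table(x)[, .(check_id, axis, n_evaluated, n_failed,
                             pass_rate = round(pass_rate, 4))])
  invisible(x)
}

#' Monitor load runs
#'
#' Summarizes the load log: last status and row-count trend per flow, failed
#' runs with their messages, and any run violating the conservation
#' invariant `rows_in == rows_loaded + rows_rejected`.
#'
#' @param load_log the `load_log` table of a warehouse.
#' @return list: `per_flow` (last status and mean rows per flow), `failed`
#'   (failed runs), `inconsistent` (conservation violations).
#' @export
monitor_loads <- function(load_log) {
  log <- as.data.table(load_log)
  if (nrow(log) == 0)
    return(list(per_flow = data.table(), failed = data.table(),
                inconsistent = data.table()))
  setorder(log, run_id)
  per_flow <- log[, .(last_status = status[.N], n_runs = .N,
                      last_rows_loaded = rows_loaded[.N],
                      mean_rows_loaded = mean(rows_loaded)), by = flow_id]
  failed <- log[!status %in% c("ok", "running"),
                .(run_id, flow_id, status, messages)]
  inconsistent <- log[status == "ok" & rows_in != rows_loaded + rows_rejected,
                      .(run_id, flow_id, rows_in, rows_loaded, rows_rejected)]
  list(per_flow = per_flow, failed = failed, inconsistent = inconsistent)
}
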