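# The normalized warehouse: row-oriented dimension and fact tables held as
# typed data.tables, persisted as a directory of UTF-8 TSV files plus
# meta.json. The on-disk form is deterministic for a given state, so two
# warehouse states can be compared by file checksums.

wh_schema <- function() {
  list(
    # dimensions
    patient = data.table(patient_id = character(), sex = character(),
                         birth_date = as.Date(character())),
    signal = data.table(signal_code = character(), label = character(),
                        unit = character()),
    care_unit = data.table(unit_label = character()),
    drug = data.table(drug_label = character()),
    event = data.table(event_label = character(), kind = character()),
    code = data.table(code = character(), code_system = character()),
    # facts
    intervention = data.table(intervention_id = character(),
                              patient_id = character(), stay_id = character(),
                              room_entry_ts = as_utc(character()),
                              room_exit_ts = as_utc(character()),
                              unit_label = character(),
                              link_reason = character()),
    measurement = data.table(measurement_id = character(),
                             intervention_id = character(),
                             signal_code = character(),
                             ts = as_utc(character()), value = numeric(),
                             unit_label = character(),
                             quality_flag = character()),
    event_record = data.table(event_id = character(),
                              intervention_id = character(),
                              event_label = character(),
                              ts = as_utc(character()), kind = character(),
                              dose = numeric(), dose_unit = character(),
                              quality_flag = character()),
    hospital_stay = data.table(stay_id = character(), patient_id = character(),
                               admission_date = as.Date(character()),
                               discharge_date = as.Date(character()),
                               discharge_status = character()),
    unit_stay = data.table(unit_stay_id = character(), stay_id = character(),
                           unit_label = character(),
                           start_date = as.Date(character()),
                           end_date = as.Date(character())),
    diagnosis = data.table(diagnosis_id = character(), stay_id = character(),
                           code = character(), dx_type = character()),
    procedure = data.table(procedure_id = character(), stay_id = character(),
                           code = character(),
                           procedure_date = as.Date(character())),
    biology = data.table(biology_id = character(), stay_id = character(),
                         analyte = character(), ts = as_utc(character()),
                         value = numeric(), unit = character()),
    death = data.table(patient_id = character(),
                       death_date = as.Date(character())),
    # operational
    load_log = data.table(run_id = integer(), flow_id = integer(),
                          started_ts = as_utc(character()),
                          finished_ts = as_utc(character()),
                          rows_in = integer(), rows_loaded = integer(),
                          rows_rejected = integer(),
                          window_start = as.Date(character()),
                          window_end = as.Date(character()),
                          status = character(), messages = character()),
    quarantine = data.table(run_id = integer(), table = character(),
                            row_key = character(), reason = character()),
    dq_result = data.table(dq_run_id = integer(), check_id = character(),
                           axis = character(), scope = character(),
                           n_evaluated = integer(), n_failed = integer(),
                           pass_rate = numeric(), failed_keys = character())
  )
}

# natural keys used for delete-then-insert overwrite semantics
wh_keys <- function() {
  list(patient = "patient_id", signal = "signal_code",
       care_unit = "unit_label", drug = "drug_label", event = "event_label",
       code = "code", intervention = "intervention_id",
       measurement = "measurement_id", event_record = "event_id",
       hospital_stay = "stay_id", unit_stay = "unit_stay_id",
       diagnosis = "diagnosis_id", procedure = "procedure_id",
       biology = "biology_id", death = "patient_id")
}

#' Initialize, persist and checksum a warehouse
#'
#' `wh_init()` creates an empty warehouse (all tables typed, zero rows) with
#' the signal dimension seeded from the configured signal list. `wh_write()`
#' serializes the warehouse to a directory of TSV files plus `meta.json`;
#' `wh_read()` restores it. `wh_checksum()` returns per-table MD5 checksums
#' of the deterministic on-disk form of the *data* tables (dimensions and
#' facts); the operational audit tables (`load_log`, `quarantine`,
#' `dq_result`) carry run ids and wall-clock times and are excluded, so the
#' checksum captures warehouse state, not load history.
#'
#' @param config an [etl_config()].
#' @return `wh_init()`/`wh_read()`: a `warehouse` object; `wh_checksum()`: a
#'   named character vector of MD5 digests.
#' @export
wh_init <- function(config = etl_config()) {
  wh <- list(tables = wh_schema())
  class(wh) <- "warehouse"
  sigcat <- signal_catalog()
  wh$tables$signal <- sigcat[signal_code %in% config$ranges$signal_code,
                             .(signal_code, label, unit)]
  wh
}

wh_ts_columns <- function() {
  list(intervention = c("room_entry_ts", "room_exit_ts"),
       measurement = "ts", event_record = "ts", biology = "ts",
       load_log = c("started_ts", "finished_ts"))
}
wh_date_columns <- function() {
  list(patient = "birth_date",
       hospital_stay = c("admission_date", "discharge_date"),
       unit_stay = c("start_date", "end_date"),
       procedure = "procedure_date", death = "death_date",
       load_log = c("window_start", "window_end"))
}

wh_serialize_table <- function(wh, nm, path) {
  dt <- copy(wh$tables[[nm]])
  for (cc in intersect(wh_ts_columns()[[nm]] %||% character(0), names(dt)))
    set(dt, j = cc, value = fmt_ts(dt[[cc]]))
  for (cc in intersect(wh_date_columns()[[nm]] %||% character(0), names(dt)))
    set(dt, j = cc, value = fmt_date(dt[[cc]]))
  fwrite(dt, path, sep = "\t", quote = FALSE)
}

#' @rdname wh_init
#' @param wh a `warehouse` object.
#' @param dir directory for the serialized warehouse.
#' @export
wh_write <- function(wh, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(wh$tables))
    wh_serialize_table(wh, nm, file.path(dir, paste0(nm, ".tsv")))
  jsonlite::write_json(
    list(tables = names(wh$tables),
         rows = lapply(wh$tables, nrow)),
    file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname wh_init
#' @export
wh_read <- function(dir) {
  assert_that(dir.exists(dir), "no such warehouse directory: %s", d = dir,
              class = "load_error")
  schema <- wh_schema()
  wh <- list(tables = schema)
  class(wh) <- "warehouse"
  for (nm in names(schema)) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    if (!file.exists(f)) next
    proto <- schema[[nm]]
    cl <- vapply(proto, function(col) class(col)[1], "")
    cl[cl %in% c("POSIXct", "Date")] <- "character"
    dt <- fread(f, sep = "\t", na.strings = "",
                colClasses = setNames(as.character(cl), names(proto)))
    for (cc in intersect(wh_ts_columns()[[nm]] %||% character(0), names(dt)))
      set(dt, j = cc, value = parse_ts(as.character(dt[[cc]])))
    for (cc in intersect(wh_date_columns()[[nm]] %||% character(0), names(dt)))
      set(dt, j = cc, value = as.Date(as.character(dt[[cc]])))
    wh$tables[[nm]] <- dt
  }
  wh
}

#' @rdname wh_init
#' @export
wh_checksum <- function(wh) {
  data_tables <- setdiff(names(wh$tables),
                         c("load_log", "quarantine", "dq_result"))
  tmp <- tempfile("whck")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  out <- character(0)
  for (nm in data_tables) {
    f <- file.path(tmp, paste0(nm, ".tsv"))
    wh_serialize_table(wh, nm, f)
    out[nm] <- unname(tools::md5sum(f))
  }
  out
}

#' @export
print.warehouse <- function(x, ...) {
  cat("<warehouse>\n")
  for (nm in names(x$tables))
    cat(sprintf("  %-14s %7d rows\n", nm, nrow(x$tables[[nm]])))
  invisible(x)
}
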