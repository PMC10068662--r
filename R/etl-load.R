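# Mirroring, staging transformation and the two incremental loading flows.
# Flow 1 carries low-volume updatable facts over a one-year sliding window;
# flow 2 carries high-volume non-updatable operating-room facts over a
# two-week sliding window. Both overwrite (delete-then-insert on natural
# keys) inside their window and never touch rows outside it.

#' Mirror source extracts into a staging snapshot
#'
#' Reads a source directory, validates it against the source-bundle schema
#' (parseable timestamps, known tables), and writes a content-identical copy
#' under `staging_dir`. The originals are never modified; mirroring twice
#' yields an identical snapshot.
#'
#' @param source_dir directory written by [write_bundle()].
#' @param staging_dir target directory.
#' @return the staged `source_bundle_set`, invisibly.
#' @export
mirror <- function(source_dir, staging_dir) {
  x <- read_bundle(source_dir)   # parse + validate
  write_bundle(x, staging_dir)
  invisible(x)
}

#' Transform a staged bundle for loading
#'
#' Applies the transform step to a staged source bundle: canonicalizes
#' signal codes and event labels through the synonym tables, flags
#' measurement and drug rows with a quality indicator (against the units and
#' ranges as received), standardizes drug dose units, and links each
#' intervention to a hospital stay. The result is load-ready staging; no
#' warehouse state is touched.
#'
#' @param x a `source_bundle_set` or bare bundle list.
#' @param config an [etl_config()].
#' @return a list of class `staging`: transformed `tables` plus the
#'   `linkage` map.
#' @export
transform_staging <- function(x, config = etl_config()) {
  bundle <- if (inherits(x, "source_bundle_set")) x$bundle else x
  b <- lapply(bundle, copy)

  # vocabulary: signal codes and event labels
  b$measurements[, signal_code := apply_vocabulary(signal_code,
                                                   config$synonyms_signals)]
  b$events[, event_label := apply_vocabulary(event_label,
                                             config$synonyms_events)]

  # quality flags against the data as received
  known <- b$measurements$signal_code %in% config$ranges$signal_code
  b$measurements[, quality_flag := "bad_unit"]  # unknown signal: unusable
  if (any(known)) {
    flagged <- flag_quality(b$measurements[known], config$ranges,
                            kind = "measurement")
    b$measurements[known, quality_flag := flagged$quality_flag]
  }
  is_drug <- b$events$kind == "drug"
  b$events[, quality_flag := "ok"]
  if (any(is_drug)) {
    flagged <- flag_quality(b$events[is_drug], config$drug_range, kind = "drug")
    b$events[is_drug, quality_flag := flagged$quality_flag]
  }

  # unit standardization (flags above document the original defect)
  b$events[is_drug] -> dr
  dr <- convert_units(dr, config$unit_rules, value_col = "dose",
                      unit_col = "dose_unit")
  b$events[is_drug, `:=`(dose = dr$dose, dose_unit = dr$dose_unit)]

  # record linkage
  lk <- link_records(b$interventions, b$stays)
  b$interventions[, stay_id := lk$links$stay_id[match(intervention_id,
                                                      lk$links$intervention_id)]]
  b$interventions[, link_reason := lk$unlinked$reason[match(intervention_id,
                                                            lk$unlinked$intervention_id)]]
  b$interventions[!is.na(stay_id), link_reason := "linked"]

  structure(list(tables = b, linkage = lk), class = "staging")
}

new_run_id <- function(wh) {
  if (nrow(wh$tables$load_log) == 0) 1L else max(wh$tables$load_log$run_id) + 1L
}

# delete-then-insert with window discipline: wh rows whose anchor date falls
# inside [win_start, win_end] are replaced by the staged rows in the window
overwrite_window <- function(wh_dt, staged_dt, anchor_wh, anchor_staged,
                             win_start, win_end, key) {
  keep <- is.na(anchor_wh) | anchor_wh < win_start | anchor_wh > win_end
  incoming <- staged_dt[!is.na(anchor_staged) & anchor_staged >= win_start &
                          anchor_staged <= win_end]
  out <- rbind(wh_dt[keep], incoming, fill = TRUE)
  setorderv(out, key)
  out
}

upsert_dim <- function(dim_dt, new_dt, key) {
  out <- rbind(dim_dt, new_dt[!new_dt[[key]] %in% dim_dt[[key]]], fill = TRUE)
  out <- unique(out, by = key)
  setorderv(out, key)
  out
}

start_run <- function(wh, flow_id, win_start, win_end) {
  assert_that(!any(wh$tables$load_log$status == "running"),
              "another load run is in progress", class = "run_rejected")
  run_id <- new_run_id(wh)
  wh$tables$load_log <- rbind(wh$tables$load_log, data.table(
    run_id = run_id, flow_id = as.integer(flow_id),
    started_ts = as_utc(Sys.time()), finished_ts = as_utc(NA),
    rows_in = 0L, rows_loaded = 0L, rows_rejected = 0L,
    window_start = win_start, window_end = win_end,
    status = "running", messages = ""))
  list(wh = wh, run_id = run_id)
}

finish_run <- function(wh, rid, rows_in, rows_loaded, rows_rejected,
                       messages = "") {
  n_in <- as.integer(rows_in); n_ld <- as.integer(rows_loaded)
  n_rj <- as.integer(rows_rejected); msg <- messages
  wh$tables$load_log[run_id == rid,
                     `:=`(finished_ts = as_utc(Sys.time()),
                          rows_in = n_in, rows_loaded = n_ld,
                          rows_rejected = n_rj,
                          status = "ok", messages = msg)]
  wh
}

quarantine_rows <- function(wh, run_id, table, keys, reason) {
  if (length(keys) == 0) return(wh)
  add <- data.table(run_id = run_id, table = table, row_key = keys,
                    reason = reason)
  q <- rbind(wh$tables$quarantine, add)
  # overwrite semantics for reruns: one quarantine record per offending row
  q <- q[order(run_id)][, .SD[.N], by = .(table, row_key)]
  setorder(q, table, row_key)
  setcolorder(q, c("run_id", "table", "row_key", "reason"))
  wh$tables$quarantine <- q
  wh
}

#' Incremental load flows
#'
#' `load_flow1()` loads the low-volume facts that the source systems may
#' retroactively update — hospital stays, unit stays, diagnoses, procedures,
#' deaths, and the patient dimension — over a one-year sliding window ending
#' at `as_of_date`. `load_flow2()` loads the high-volume, non-updatable
#' operating-room facts — interventions, measurements, drug/step events,
#' biology — over a fourteen-day sliding window. Both flows overwrite
#' existing data inside the window (delete-then-insert on natural keys) and
#' never insert, update or delete a row outside it, so weekly runs are
#' idempotent and older history is preserved untouched. Rows without a
#' usable key (e.g. measurements that lost their intervention id) are
#' quarantined and counted as rejected, never silently dropped.
#'
#' @param wh a `warehouse` from [wh_init()] or [wh_read()].
#' @param staging a `staging` object from [transform_staging()].
#' @param as_of_date the run's reference date (`Date`).
#' @return the updated `warehouse`; the run's `load_log` entry is the last
#'   row of `wh$tables$load_log`.
#' @export
load_flow1 <- function(wh, staging, as_of_date) {
  as_of_date <- as.Date(as_of_date)
  win_start <- as_of_date - 365L
  st <- staging$tables
  run <- start_run(wh, 1L, win_start, as_of_date)
  wh <- run$wh; run_id <- run$run_id

  # anchor of stay-children = their stay's admission date (in staging)
  stay_adm <- setNames(st$stays$admission_date, st$stays$stay_id)
  wh_adm <- setNames(wh$tables$hospital_stay$admission_date,
                     wh$tables$hospital_stay$stay_id)

  rows_in <- 0L; rows_rejected <- 0L

  in_win <- function(anchor) !is.na(anchor) & anchor >= win_start &
    anchor <= as_of_date

  # reject stays with missing key or missing patient
  bad_stay <- st$stays[in_win(admission_date) &
                         (is.na(stay_id) | is.na(patient_id)), stay_id]
  ok_stays <- st$stays[!stay_id %in% bad_stay]
  wh <- quarantine_rows(wh, run_id, "hospital_stay", bad_stay[!is.na(bad_stay)],
                        "missing_key")

  loads <- list(
    hospital_stay = list(staged = ok_stays,
                         a_st = ok_stays$admission_date,
                         a_wh = wh$tables$hospital_stay$admission_date),
    unit_stay = list(staged = st$unit_stays,
                     a_st = stay_adm[st$unit_stays$stay_id],
                     a_wh = wh_adm[wh$tables$unit_stay$stay_id]),
    diagnosis = list(staged = st$diagnoses,
                     a_st = stay_adm[st$diagnoses$stay_id],
                     a_wh = wh_adm[wh$tables$diagnosis$stay_id]),
    procedure = list(staged = st$procedures,
                     a_st = stay_adm[st$procedures$stay_id],
                     a_wh = wh_adm[wh$tables$procedure$stay_id]),
    death = list(staged = st$deaths,
                 a_st = st$deaths$death_date,
                 a_wh = wh$tables$death$death_date)
  )
  nm_map <- c(hospital_stay = "stays", unit_stay = "unit_stays",
              diagnosis = "diagnoses", procedure = "procedures",
              death = "deaths")
  for (nm in names(loads)) {
    L <- loads[[nm]]
    n_in <- sum(in_win(L$a_st))
    rows_in <- rows_in + n_in
    wh$tables[[nm]] <- overwrite_window(
      wh$tables[[nm]],
      L$staged[, names(wh$tables[[nm]]), with = FALSE],
      L$a_wh, L$a_st, win_start, as_of_date, wh_keys()[[nm]])
  }
  rows_rejected <- length(bad_stay)
  rows_in <- rows_in + rows_rejected

  # patient dimension: upsert for patients referenced by loaded stays
  pats <- st$patients[patient_id %in% wh$tables$hospital_stay$patient_id]
  wh$tables$patient <- upsert_dim(wh$tables$patient, pats, "patient_id")

  finish_run(wh, run_id, rows_in, rows_in - rows_rejected, rows_rejected)
}

#' @rdname load_flow1
#' @export
load_flow2 <- function(wh, staging, as_of_date) {
  as_of_date <- as.Date(as_of_date)
  win_start <- as_of_date - 14L
  st <- staging$tables
  run <- start_run(wh, 2L, win_start, as_of_date)
  wh <- run$wh; run_id <- run$run_id

  in_win <- function(anchor) !is.na(anchor) & anchor >= win_start &
    anchor <= as_of_date

  rows_in <- 0L; rows_rejected <- 0L

  # interventions
  iv <- copy(st$interventions)
  iv_anchor <- as.Date(iv$room_entry_ts, tz = "UTC")
  n_in <- sum(in_win(iv_anchor)); rows_in <- rows_in + n_in
  bad_iv <- iv[in_win(iv_anchor) & is.na(patient_id), intervention_id]
  wh <- quarantine_rows(wh, run_id, "intervention", bad_iv, "missing_patient_id")
  rows_rejected <- rows_rejected + length(bad_iv)
  iv <- iv[!intervention_id %in% bad_iv]
  wh$tables$intervention <- overwrite_window(
    wh$tables$intervention,
    iv[, names(wh$tables$intervention), with = FALSE],
    as.Date(wh$tables$intervention$room_entry_ts, tz = "UTC"),
    as.Date(iv$room_entry_ts, tz = "UTC"),
    win_start, as_of_date, "intervention_id")

  # measurements: orphan rows (no intervention id) are quarantined
  ms <- st$measurements
  ms_anchor <- as.Date(ms$ts, tz = "UTC")
  n_in <- sum(in_win(ms_anchor)); rows_in <- rows_in + n_in
  orphan <- ms[in_win(ms_anchor) & quality_flag == "orphan", measurement_id]
  wh <- quarantine_rows(wh, run_id, "measurement", orphan, "orphan")
  rows_rejected <- rows_rejected + length(orphan)
  ms <- ms[quality_flag != "orphan"]
  wh$tables$measurement <- overwrite_window(
    wh$tables$measurement,
    ms[, names(wh$tables$measurement), with = FALSE],
    as.Date(wh$tables$measurement$ts, tz = "UTC"),
    as.Date(ms$ts, tz = "UTC"),
    win_start, as_of_date, "measurement_id")

  # drug and step events
  ev <- st$events
  ev_anchor <- as.Date(ev$ts, tz = "UTC")
  n_in <- sum(in_win(ev_anchor)); rows_in <- rows_in + n_in
  ev_orphan <- ev[in_win(ev_anchor) & quality_flag == "orphan", event_id]
  wh <- quarantine_rows(wh, run_id, "event_record", ev_orphan, "orphan")
  rows_rejected <- rows_rejected + length(ev_orphan)
  ev <- ev[quality_flag != "orphan"]
  wh$tables$event_record <- overwrite_window(
    wh$tables$event_record,
    ev[, names(wh$tables$event_record), with = FALSE],
    as.Date(wh$tables$event_record$ts, tz = "UTC"),
    as.Date(ev$ts, tz = "UTC"),
    win_start, as_of_date, "event_id")

  # biology
  bio <- st$biology
  bio_anchor <- as.Date(bio$ts, tz = "UTC")
  n_in <- sum(in_win(bio_anchor)); rows_in <- rows_in + n_in
  wh$tables$biology <- overwrite_window(
    wh$tables$biology,
    bio[, names(wh$tables$biology), with = FALSE],
    as.Date(wh$tables$biology$ts, tz = "UTC"),
    as.Date(bio$ts, tz = "UTC"),
    win_start, as_of_date, "biology_id")

  # dimensions referenced by loaded facts
  wh$tables$care_unit <- upsert_dim(
    wh$tables$care_unit,
    data.table(unit_label = unique(wh$tables$intervention$unit_label)),
    "unit_label")
  wh$tables$drug <- upsert_dim(
    wh$tables$drug,
    data.table(drug_label = unique(
      wh$tables$event_record[kind == "drug", event_label])),
    "drug_label")
  wh$tables$event <- upsert_dim(
    wh$tables$event,
    unique(wh$tables$event_record[, .(event_label, kind)]),
    "event_label")
  wh$tables$patient <- upsert_dim(
    wh$tables$patient,
    st$patients[patient_id %in% wh$tables$intervention$patient_id],
    "patient_id")

  finish_run(wh, run_id, rows_in, rows_in - rows_rejected, rows_rejected)
}
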