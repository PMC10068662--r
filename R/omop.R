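# OMOP CDM v5.4 shaped export. The operating-room passage becomes a
# VISIT_DETAIL child of its hospital stay's VISIT_OCCURRENCE, exactly like
# an ICU unit stay; vitals go to MEASUREMENT, drug administrations to
# DRUG_EXPOSURE, step events to PROCEDURE_OCCURRENCE or OBSERVATION
# depending on their concept-map domain, and CCAM-like procedure codes to
# PROCEDURE_OCCURRENCE. Every OR-derived row carries the visit_detail_id of
# its passage.
#
# Concept ids come from a bundled mini-vocabulary. It is a SYNTHETIC
# stand-in for a real OMOP vocabulary download (the production local-to-
# standard mapping tables are not public); unmapped labels fall back to a
# reserved local range starting at 2,000,000,000.

LOCAL_CONCEPT_BASE <- 2000000000L

#' Bundled mini concept map (synthetic stand-in)
#'
#' Maps canonical local labels (signals, units, drugs, step events, visit
#' types) to concept ids in OMOP-style vocabularies (LOINC, UCUM, RxNorm,
#' SNOMED, local). Shipped as `extdata/mini_vocab_synthetic.csv`; it is a
#' constructed example, not the OHDSI vocabulary.
#'
#' @return data.table (`local_label`, `domain`, `vocabulary`, `concept_id`,
#'   `concept_name`).
#' @export
default_concept_map <- function() {
  f <- system.file("extdata", "mini_vocab_synthetic.csv", package = "periopdw")
  fread(f, colClasses = list(character = c(1, 2, 3, 5), integer = 4))
}

concept_lookup <- function(concept_map, dom) {
  cm <- as.data.table(concept_map)
  cm <- cm[cm[["domain"]] == dom]
  setNames(cm$concept_id, cm$local_label)
}

# deterministic fallback ids for labels absent from the concept map
fallback_ids <- function(labels, offset) {
  u <- sort(unique(labels))
  setNames(LOCAL_CONCEPT_BASE + offset + seq_along(u), u)
}

map_concept <- function(labels, lookup, offset) {
  out <- unname(lookup[labels])
  miss <- is.na(out)
  if (any(miss)) {
    fb <- fallback_ids(labels[miss], offset)
    out[miss] <- unname(fb[labels[miss]])
  }
  list(ids = as.integer(out), n_unmapped = sum(miss),
       unmapped = sort(unique(labels[is.na(unname(lookup[labels]))])))
}

#' Map warehouse stays and interventions to OMOP visits
#'
#' One `VISIT_OCCURRENCE` per hospital stay; one `VISIT_DETAIL` per
#' operating-room passage and per unit stay, each a child of its stay's
#' visit. Interventions without a linked stay are exported under a
#' synthetic standalone visit and counted in the report.
#'
#' @param wh a `warehouse`.
#' @param concept_map a concept map table ([default_concept_map()]).
#' @return list: `PERSON`, `VISIT_OCCURRENCE`, `VISIT_DETAIL` data.tables,
#'   plus `report` (counts, including synthetic standalone visits).
#' @export
map_visits <- function(wh, concept_map = default_concept_map()) {
  pats <- copy(wh$tables$patient); setorder(pats, patient_id)
  person <- data.table(
    person_id = seq_len(nrow(pats)),
    gender_concept_id = ifelse(pats$sex == "M", 8507L, 8532L),
    year_of_birth = as.integer(format(pats$birth_date, "%Y")),
    month_of_birth = as.integer(format(pats$birth_date, "%m")),
    day_of_birth = as.integer(format(pats$birth_date, "%d")),
    person_source_value = pats$patient_id
  )
  pid <- setNames(person$person_id, person$person_source_value)

  stays <- copy(wh$tables$hospital_stay); setorder(stays, stay_id)
  vo <- data.table(
    visit_occurrence_id = seq_len(nrow(stays)),
    person_id = unname(pid[stays$patient_id]),
    visit_concept_id = 9201L,
    visit_start_date = stays$admission_date,
    visit_end_date = stays$discharge_date,
    visit_type_concept_id = 32817L,
    visit_source_value = stays$stay_id
  )

  iv <- copy(wh$tables$intervention); setorder(iv, intervention_id)
  unlinked <- iv[is.na(stay_id)]
  if (nrow(unlinked) > 0) {
    synth <- data.table(
      visit_occurrence_id = nrow(vo) + seq_len(nrow(unlinked)),
      person_id = unname(pid[unlinked$patient_id]),
      visit_concept_id = 9201L,
      visit_start_date = as.Date(unlinked$room_entry_ts, tz = "UTC"),
      visit_end_date = as.Date(unlinked$room_exit_ts, tz = "UTC"),
      visit_type_concept_id = 32817L,
      visit_source_value = paste0("synthetic:", unlinked$intervention_id)
    )
    vo <- rbind(vo, synth)
  }
  vo_id <- setNames(vo$visit_occurrence_id, vo$visit_source_value)
  iv[, vo_key := ifelse(is.na(stay_id),
                        paste0("synthetic:", intervention_id), stay_id)]

  vlk <- concept_lookup(concept_map, "Visit")
  or_concept <- unname(vlk["operating room"])
  us <- copy(wh$tables$unit_stay); setorder(us, unit_stay_id)
  unit_concepts <- map_concept(us$unit_label, vlk, 300L)

  vd <- rbind(
    data.table(
      source_kind = "intervention",
      source_value = iv$intervention_id,
      person_id = unname(pid[iv$patient_id]),
      visit_detail_concept_id = as.integer(or_concept),
      visit_detail_start_datetime = iv$room_entry_ts,
      visit_detail_end_datetime = iv$room_exit_ts,
      visit_occurrence_id = unname(vo_id[iv$vo_key])
    ),
    data.table(
      source_kind = "unit_stay",
      source_value = us$unit_stay_id,
      person_id = unname(pid[stays$patient_id[match(us$stay_id, stays$stay_id)]]),
      visit_detail_concept_id = unit_concepts$ids,
      visit_detail_start_datetime = as_utc(as.POSIXct(us$start_date, tz = "UTC")),
      visit_detail_end_datetime = as_utc(as.POSIXct(us$end_date, tz = "UTC")),
      visit_occurrence_id = unname(vo_id[us$stay_id])
    )
  )
  vd[, visit_detail_id := seq_len(.N)]
  vd[, visit_detail_type_concept_id := 32817L]
  setcolorder(vd, c("visit_detail_id", "person_id", "visit_detail_concept_id",
                    "visit_detail_start_datetime", "visit_detail_end_datetime",
                    "visit_detail_type_concept_id", "visit_occurrence_id",
                    "source_kind", "source_value"))

  list(PERSON = person, VISIT_OCCURRENCE = vo, VISIT_DETAIL = vd,
       report = list(n_person = nrow(person), n_visit = nrow(vo),
                     n_visit_detail = nrow(vd),
                     n_synthetic_standalone = nrow(unlinked),
                     n_unmapped_units = unit_concepts$n_unmapped))
}

#' Map warehouse records into OMOP event tables
#'
#' Ok-flagged vitals become `MEASUREMENT` rows, ok-flagged drug
#' administrations `DRUG_EXPOSURE` rows (point-in-time: start = end =
#' administration timestamp), step events route to `PROCEDURE_OCCURRENCE`
#' when their concept-map domain is Procedure and to `OBSERVATION`
#' otherwise, and PMSI-side procedure codes become stay-level
#' `PROCEDURE_OCCURRENCE` rows. Labels absent from the concept map get
#' deterministic fallback ids in the reserved local range and are counted.
#'
#' @param wh a `warehouse`.
#' @param visits result of [map_visits()].
#' @param concept_map a concept map table.
#' @return list of CDM tables plus `report` (per-category exported /
#'   excluded / unmapped counts).
#' @export
map_records <- function(wh, visits, concept_map = default_concept_map()) {
  vd <- visits$VISIT_DETAIL[source_kind == "intervention"]
  vd_id <- setNames(vd$visit_detail_id, vd$source_value)
  vd_vo <- setNames(vd$visit_occurrence_id, vd$source_value)
  vd_person <- setNames(vd$person_id, vd$source_value)
  vo_id <- setNames(visits$VISIT_OCCURRENCE$visit_occurrence_id,
                    visits$VISIT_OCCURRENCE$visit_source_value)
  pid <- setNames(visits$PERSON$person_id, visits$PERSON$person_source_value)

  ms <- wh$tables$measurement[quality_flag == "ok"]
  setorder(ms, measurement_id)
  sig <- map_concept(ms$signal_code, concept_lookup(concept_map, "Measurement"), 400L)
  un <- map_concept(ms$unit_label, concept_lookup(concept_map, "Unit"), 500L)
  measurement <- data.table(
    measurement_id = seq_len(nrow(ms)),
    person_id = unname(vd_person[ms$intervention_id]),
    measurement_concept_id = sig$ids,
    measurement_datetime = ms$ts,
    measurement_type_concept_id = 32817L,
    value_as_number = ms$value,
    unit_concept_id = un$ids,
    visit_occurrence_id = unname(vd_vo[ms$intervention_id]),
    visit_detail_id = unname(vd_id[ms$intervention_id]),
    measurement_source_value = ms$signal_code,
    unit_source_value = ms$unit_label
  )

  ev <- wh$tables$event_record
  dr <- ev[kind == "drug" & quality_flag == "ok"]
  setorder(dr, event_id)
  drc <- map_concept(dr$event_label, concept_lookup(concept_map, "Drug"), 600L)
  drug_exposure <- data.table(
    drug_exposure_id = seq_len(nrow(dr)),
    person_id = unname(vd_person[dr$intervention_id]),
    drug_concept_id = drc$ids,
    drug_exposure_start_datetime = dr$ts,
    drug_exposure_end_datetime = dr$ts,
    drug_type_concept_id = 32817L,
    quantity = dr$dose,
    visit_occurrence_id = unname(vd_vo[dr$intervention_id]),
    visit_detail_id = unname(vd_id[dr$intervention_id]),
    drug_source_value = dr$event_label,
    dose_unit_source_value = dr$dose_unit
  )

  # step-event routing: Procedure-domain concepts -> PROCEDURE_OCCURRENCE,
  # free-text milestones -> OBSERVATION
  steps <- ev[kind == "step" & quality_flag == "ok"]
  setorder(steps, event_id)
  proc_domain <- concept_lookup(concept_map, "Procedure")
  is_proc <- steps$event_label %in% names(proc_domain)
  obs <- steps[!is_proc]
  obsc <- map_concept(obs$event_label, concept_lookup(concept_map, "Observation"), 700L)
  observation <- data.table(
    observation_id = seq_len(nrow(obs)),
    person_id = unname(vd_person[obs$intervention_id]),
    observation_concept_id = obsc$ids,
    observation_datetime = obs$ts,
    observation_type_concept_id = 32817L,
    value_as_string = obs$event_label,
    visit_occurrence_id = unname(vd_vo[obs$intervention_id]),
    visit_detail_id = unname(vd_id[obs$intervention_id]),
    observation_source_value = obs$event_label
  )

  px <- copy(wh$tables$procedure); setorder(px, procedure_id)
  pxc <- map_concept(px$code, proc_domain, 800L)
  step_px <- steps[is_proc]
  procedure_occurrence <- rbind(
    data.table(
      person_id = unname(pid[wh$tables$hospital_stay$patient_id[
        match(px$stay_id, wh$tables$hospital_stay$stay_id)]]),
      procedure_concept_id = pxc$ids,
      procedure_datetime = as_utc(as.POSIXct(px$procedure_date, tz = "UTC")),
      procedure_type_concept_id = 32817L,
      visit_occurrence_id = unname(vo_id[px$stay_id]),
      visit_detail_id = NA_integer_,
      procedure_source_value = px$code
    ),
    if (nrow(step_px) > 0) data.table(
      person_id = unname(vd_person[step_px$intervention_id]),
      procedure_concept_id = as.integer(unname(proc_domain[step_px$event_label])),
      procedure_datetime = step_px$ts,
      procedure_type_concept_id = 32817L,
      visit_occurrence_id = unname(vd_vo[step_px$intervention_id]),
      visit_detail_id = unname(vd_id[step_px$intervention_id]),
      procedure_source_value = step_px$event_label
    )
  )
  procedure_occurrence[, procedure_occurrence_id := seq_len(.N)]
  setcolorder(procedure_occurrence, "procedure_occurrence_id")

  list(MEASUREMENT = measurement, DRUG_EXPOSURE = drug_exposure,
       PROCEDURE_OCCURRENCE = procedure_occurrence, OBSERVATION = observation,
       report = list(
         measurements_exported = nrow(measurement),
         measurements_excluded_not_ok =
           nrow(wh$tables$measurement) - nrow(ms),
         drugs_exported = nrow(drug_exposure),
         drugs_excluded_not_ok = nrow(ev[kind == "drug"]) - nrow(dr),
         steps_exported = nrow(observation) + nrow(step_px),
         procedures_exported = nrow(px),
         diagnoses_excluded = nrow(wh$tables$diagnosis),
         n_unmapped_concepts = sig$n_unmapped + un$n_unmapped +
           drc$n_unmapped + obsc$n_unmapped + pxc$n_unmapped,
         unmapped_labels = unique(c(sig$unmapped, un$unmapped, drc$unmapped,
                                    obsc$unmapped, pxc$unmapped))))
}

#' Export the warehouse to OMOP CDM v5.4 shaped tables
#'
#' Runs [map_visits()] and [map_records()] and assembles a `cdm_bundle`.
#' Re-exporting an unchanged warehouse gives identical tables.
#'
#' @param wh a `warehouse`.
#' @param concept_map a concept map table.
#' @return a `cdm_bundle`: CDM tables plus an export `report`.
#' @export
omop_export <- function(wh, concept_map = default_concept_map()) {
  visits <- map_visits(wh, concept_map)
  recs <- map_records(wh, visits, concept_map)
  bundle <- list(
    PERSON = visits$PERSON,
    VISIT_OCCURRENCE = visits$VISIT_OCCURRENCE,
    VISIT_DETAIL = visits$VISIT_DETAIL[, !c("source_kind", "source_value")],
    MEASUREMENT = recs$MEASUREMENT,
    DRUG_EXPOSURE = recs$DRUG_EXPOSURE,
    PROCEDURE_OCCURRENCE = recs$PROCEDURE_OCCURRENCE,
    OBSERVATION = recs$OBSERVATION,
    report = c(visits$report, recs$report)
  )
  class(bundle) <- "cdm_bundle"
  bundle
}

cdm_table_names <- function() {
  c("PERSON", "VISIT_OCCURRENCE", "VISIT_DETAIL", "MEASUREMENT",
    "DRUG_EXPOSURE", "PROCEDURE_OCCURRENCE", "OBSERVATION")
}

#' Write a CDM bundle as one CSV per table
#'
#' UTF-8, header row, ISO-8601 datetimes; byte-deterministic for a given
#' bundle.
#'
#' @param bundle a `cdm_bundle`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cdm <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in cdm_table_names()) {
    dt <- copy(as.data.table(bundle[[nm]]))
    for (cc in names(dt))
      if (inherits(dt[[cc]], "POSIXct")) set(dt, j = cc, value = fmt_ts(dt[[cc]]))
    fwrite(dt, file.path(dir, paste0(nm, ".csv")))
  }
  jsonlite::write_json(bundle$report, file.path(dir, "export_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Verify referential integrity of a CDM bundle
#'
#' Checks that every `person_id`, `visit_occurrence_id` and (where set)
#' `visit_detail_id` resolves, and reports per-table row counts and the
#' number of fallback (unmapped) concepts.
#'
#' @param bundle a `cdm_bundle`.
#' @return list: `violations` (data.table naming table, column and row id),
#'   `n_violations`, `row_counts`, `n_unmapped_concepts`.
#' @export
check_cdm <- function(bundle) {
  persons <- bundle$PERSON$person_id
  visits <- bundle$VISIT_OCCURRENCE$visit_occurrence_id
  details <- bundle$VISIT_DETAIL$visit_detail_id
  v <- list()
  add <- function(tab, col, ids) {
    if (length(ids))
      v[[length(v) + 1L]] <<- data.table(table = tab, column = col,
                                         row = as.character(ids))
  }
  fk <- function(tab, id_col, col, universe, allow_na = TRUE) {
    dt <- as.data.table(bundle[[tab]])
    if (nrow(dt) == 0 || !col %in% names(dt)) return()
    bad_na <- if (allow_na) rep(FALSE, nrow(dt)) else is.na(dt[[col]])
    bad <- dt[bad_na | (!is.na(dt[[col]]) & !dt[[col]] %in% universe)][[id_col]]
    add(tab, col, bad)
  }
  fk("VISIT_OCCURRENCE", "visit_occurrence_id", "person_id", persons,
     allow_na = FALSE)
  fk("VISIT_DETAIL", "visit_detail_id", "person_id", persons, allow_na = FALSE)
  fk("VISIT_DETAIL", "visit_detail_id", "visit_occurrence_id", visits,
     allow_na = FALSE)
  for (tab in c("MEASUREMENT", "DRUG_EXPOSURE", "PROCEDURE_OCCURRENCE",
                "OBSERVATION")) {
    id_col <- switch(tab, MEASUREMENT = "measurement_id",
                     DRUG_EXPOSURE = "drug_exposure_id",
                     PROCEDURE_OCCURRENCE = "procedure_occurrence_id",
                     OBSERVATION = "observation_id")
    fk(tab, id_col, "person_id", persons, allow_na = FALSE)
    fk(tab, id_col, "visit_occurrence_id", visits, allow_na = FALSE)
    # OR-derived rows must resolve their passage; stay-level procedure rows
    # legitimately carry no visit_detail_id
    fk(tab, id_col, "visit_detail_id", details,
       allow_na = (tab == "PROCEDURE_OCCURRENCE"))
  }
  violations <- if (length(v)) rbindlist(v)
                else data.table(table = character(), column = character(),
                                row = character())
  list(violations = violations, n_violations = nrow(violations),
       row_counts = sapply(cdm_table_names(),
                           function(nm) nrow(bundle[[nm]])),
       n_unmapped_concepts = bundle$report$n_unmapped_concepts %||% NA_integer_)
}

#' @export
print.cdm_bundle <- function(x, ...) {
  cat("<cdm_bundle>\n")
  for (nm in cdm_table_names())
    cat(sprintf("  %-20s %7d rows\n", nm, nrow(x[[nm]])))
  cat(sprintf("  unmapped concepts: %s\n", x$report$n_unmapped_concepts))
  invisible(x)
}
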