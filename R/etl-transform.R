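# Transform-step primitives: vocabulary cleaning, unit conversion, quality
# flagging, record linkage and code grouping. These run between the staged
# source copy and the warehouse load, and each is usable standalone.

normalize_label <- function(x) {
  out <- iconv(x, from = "", to = "ASCII//TRANSLIT")
  out <- gsub("\\s+", " ", trimws(out))
  tolower(out)
}

#' Normalize labels and map synonyms to canonical forms
#'
#' Labels are normalized (trim, collapse internal whitespace, case-fold,
#' strip diacritics) and then looked up in the synonym table; a normalized
#' label with no synonym entry becomes its own canonical form. This is how
#' duplicate manual entries and monitor-brand label variants (e.g. the same
#' signal labeled differently by General Electric and Mindray monitors)
#' collapse onto one vocabulary entry.
#'
#' @param labels character vector.
#' @param synonym_table data.table/data.frame (`variant`, `canonical`), or
#'   `NULL` for pure normalization. Variants are themselves normalized before
#'   matching.
#' @return a data.table (`label`, `canonical`), one row per distinct input
#'   label.
#' @export
#' @examples
#' clean_vocabulary(c("Heart  Rate ", "heart rate"))
clean_vocabulary <- function(labels, synonym_table = NULL) {
  if (!is.null(synonym_table)) {
    syn <- as.data.table(synonym_table)
    assert_that(all(c("variant", "canonical") %in% names(syn)),
                "synonym_table needs columns variant, canonical",
                class = "config_error")
    syn[, variant := normalize_label(variant)]
    conflict <- syn[, uniqueN(canonical), by = variant][V1 > 1, variant]
    assert_that(length(conflict) == 0,
                "conflicting synonym entries for: %s", class = "config_error",
                v = paste(conflict, collapse = ", "))
    syn <- unique(syn, by = "variant")
  } else {
    syn <- data.table(variant = character(), canonical = character())
  }
  out <- data.table(label = unique(labels))
  out[, norm := normalize_label(label)]
  out[, canonical := syn$canonical[match(norm, syn$variant)]]
  out[is.na(canonical), canonical := norm]
  out[, norm := NULL]
  out[]
}

# vectorized application of a clean_vocabulary() map
apply_vocabulary <- function(labels, synonym_table = NULL) {
  map <- clean_vocabulary(labels, synonym_table)
  map$canonical[match(labels, map$label)]
}

#' Convert values to standard units
#'
#' Applies single-step conversion rules (e.g. gram to milligram when both
#' units appear for the same drug): rows whose unit matches a `from_unit` get
#' `value * factor` and the `to_unit` label; rows already in a target unit,
#' or in a unit no rule covers, pass through unchanged (unknown units are
#' caught later by quality flagging).
#'
#' @param rows data.table with a value column and a unit column.
#' @param unit_rules data.table (`from_unit`, `to_unit`, `factor`),
#'   factors > 0; rules must be single-step (no unit both a source and a
#'   target) and unambiguous.
#' @param value_col,unit_col column names in `rows`.
#' @return a converted copy of `rows`.
#' @export
#' @examples
#' rules <- data.frame(from_unit = "g", to_unit = "mg", factor = 1000)
#' convert_units(data.frame(value = 1, unit = "g"), rules,
#'               value_col = "value", unit_col = "unit")
convert_units <- function(rows, unit_rules, value_col = "value",
                          unit_col = "unit_label") {
  rules <- as.data.table(unit_rules)
  assert_that(all(rules$factor > 0), "conversion factors must be positive",
              class = "config_error")
  dup <- rules[, .N, by = from_unit][N > 1, from_unit]
  assert_that(length(dup) == 0,
              "duplicate conversion rules for unit(s): %s",
              class = "config_error", u = paste(dup, collapse = ", "))
  assert_that(length(intersect(rules$from_unit, rules$to_unit)) == 0,
              "chained or cyclic unit rules are not allowed",
              class = "config_error")
  out <- as.data.table(copy(rows))
  m <- match(out[[unit_col]], rules$from_unit)
  hit <- !is.na(m)
  if (any(hit)) {
    set(out, which(hit), value_col, out[[value_col]][hit] * rules$factor[m[hit]])
    set(out, which(hit), unit_col, rules$to_unit[m[hit]])
  }
  out
}

quality_flags <- function() {
  c("ok", "bad_unit", "out_of_range", "missing_value", "orphan")
}

#' Flag measurement or drug rows with a quality indicator
#'
#' Every row receives exactly one flag, checked in this order: `orphan`
#' (no intervention id), `missing_value`, `bad_unit` (unit differs from the
#' expected unit for the signal or drug), `out_of_range` (value outside the
#' plausible range), else `ok`. Flags document the row as received from the
#' source: a row whose unit is later standardized keeps its `bad_unit` flag.
#' Only `ok` rows feed feature extraction.
#'
#' @param rows measurements (`signal_code`, `value`, `unit_label`,
#'   `intervention_id`) or drug events (`dose`, `dose_unit`,
#'   `intervention_id`).
#' @param range_table for measurements: data.table (`signal_code`, `lo`,
#'   `hi`, `unit`) covering every signal present; for drugs: a list
#'   (`unit`, `lo`, `hi`).
#' @param kind `"measurement"` or `"drug"`.
#' @return a copy of `rows` with a `quality_flag` column.
#' @export
flag_quality <- function(rows, range_table, kind = c("measurement", "drug")) {
  kind <- match.arg(kind)
  out <- as.data.table(copy(rows))
  if (kind == "measurement") {
    rt <- as.data.table(range_table)
    missing_sig <- setdiff(unique(out$signal_code), rt$signal_code)
    assert_that(length(missing_sig) == 0,
                "signal(s) absent from range table: %s", class = "config_error",
                s = paste(missing_sig, collapse = ", "))
    m <- match(out$signal_code, rt$signal_code)
    flag <- rep("ok", nrow(out))
    flag[out$value < rt$lo[m] | out$value > rt$hi[m]] <- "out_of_range"
    flag[out$unit_label != rt$unit[m]] <- "bad_unit"
    flag[is.na(out$value)] <- "missing_value"
    flag[is.na(out$intervention_id)] <- "orphan"
  } else {
    flag <- rep("ok", nrow(out))
    flag[out$dose < range_table$lo | out$dose > range_table$hi] <- "out_of_range"
    flag[out$dose_unit != range_table$unit] <- "bad_unit"
    flag[is.na(out$dose)] <- "missing_value"
    flag[is.na(out$intervention_id)] <- "orphan"
  }
  out[, quality_flag := flag]
  out[]
}

#' Link anesthesia records to hospital stays
#'
#' An intervention links to a stay of the same patient whose
#' `[admission_date, discharge_date]` contains the operating-room entry
#' date. When several stays qualify, the one with the latest admission not
#' after the intervention date wins (the most specific admission); residual
#' ties go to the smallest `stay_id`. Unlinkable interventions are reported
#' with a reason, never dropped.
#'
#' @param interventions data.table with `intervention_id`, `patient_id`,
#'   `room_entry_ts`.
#' @param stays data.table with `stay_id`, `patient_id`, `admission_date`,
#'   `discharge_date`.
#' @return a list of class `linkage_map`: `links` (`intervention_id`,
#'   `stay_id`) and `unlinked` (`intervention_id`, `reason` in
#'   `no_candidate`, `missing_patient_id`).
#' @export
link_records <- function(interventions, stays) {
  iv <- as.data.table(interventions)[, .(intervention_id, patient_id,
                                         or_date = as.Date(room_entry_ts, tz = "UTC"))]
  st <- as.data.table(stays)[, .(stay_id, patient_id, admission_date,
                                 discharge_date)]
  no_pat <- iv[is.na(patient_id), intervention_id]
  cand <- merge(iv[!is.na(patient_id)], st, by = "patient_id",
                allow.cartesian = TRUE)
  cand <- cand[or_date >= admission_date & or_date <= discharge_date]
  setorder(cand, intervention_id, -admission_date, stay_id)
  links <- cand[, .SD[1], by = intervention_id][, .(intervention_id, stay_id)]
  unlinked <- rbind(
    data.table(intervention_id = no_pat,
               reason = rep("missing_patient_id", length(no_pat))),
    data.table(intervention_id = setdiff(iv[!is.na(patient_id), intervention_id],
                                         links$intervention_id),
               reason = "no_candidate")
  )
  setorder(links, intervention_id)
  setorder(unlinked, intervention_id)
  structure(list(links = links, unlinked = unlinked), class = "linkage_map")
}

#' @export
print.linkage_map <- function(x, ...) {
  cat(sprintf("<linkage_map> %d linked, %d unlinked\n",
              nrow(x$links), nrow(x$unlinked)))
  if (nrow(x$unlinked)) print(x$unlinked[, .N, by = reason])
  invisible(x)
}

#' Derive a per-stay boolean feature from a procedure-code grouping
#'
#' A stay is flagged when at least one of its procedure codes belongs to the
#' grouping's code set — e.g. the bundled "extracorporeal circulation"
#' grouping collects every procedure code performed under cardiopulmonary
#' bypass.
#'
#' @param procedures data.table (`stay_id`, `code`).
#' @param grouping_def list with `name` and non-empty character `codes`.
#' @return data.table (`stay_id`, one logical column named after the
#'   grouping), one row per distinct stay in `procedures`.
#' @export
#' @examples
#' px <- data.frame(stay_id = c("S1", "S2"), code = c("DZEA002", "NEKA020"))
#' group_codes(px, list(name = "ecc", codes = ecc_code_set()))
group_codes <- function(procedures, grouping_def) {
  assert_that(is.list(grouping_def) && !is.null(grouping_def$name),
              "grouping_def needs a name", class = "config_error")
  assert_that(length(grouping_def$codes) > 0, "empty code set in grouping '%s'",
              class = "config_error", g = grouping_def$name)
  px <- as.data.table(procedures)
  out <- px[, .(flag = any(code %in% grouping_def$codes)), by = stay_id]
  setnames(out, "flag", grouping_def$name)
  setorder(out, stay_id)
  out[]
}
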