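# ETL configuration: plausibility ranges, unit-conversion rules, vocabulary
# synonym tables, code groupings and required step events. Defaults ship with
# the package; a YAML file with the same keys can override any part.

#' ETL configuration
#'
#' Bundles everything the transform step needs: per-signal plausibility
#' ranges and expected units, drug dose range and standard unit, unit
#' conversion rules, synonym tables for signal codes and event labels
#' (including monitor-brand variants such as `MAP-GE` / `MAP-Mindray`),
#' procedure-code groupings, and the list of step events every anesthesia
#' record must document.
#'
#' @param ranges data.table (`signal_code`, `lo`, `hi`, `unit`).
#' @param drug_range list with `unit`, `lo`, `hi` for drug doses after
#'   standardization.
#' @param unit_rules data.table (`from_unit`, `to_unit`, `factor`).
#' @param synonyms_signals,synonyms_events data.tables (`variant`,
#'   `canonical`); variants are matched after normalization.
#' @param groupings named list of character code sets (e.g.
#'   `extracorporeal_circulation`).
#' @param required_events character vector of step-event labels that must be
#'   present once per intervention.
#' @return a list of class `etl_config`.
#' @export
#' @examples
#' cfg <- etl_config()
#' cfg$ranges
etl_config <- function(ranges = NULL, drug_range = NULL, unit_rules = NULL,
                       synonyms_signals = NULL, synonyms_events = NULL,
                       groupings = NULL, required_events = NULL) {
  sigcat <- signal_catalog()
  if (is.null(ranges)) ranges <- sigcat[, .(signal_code, lo, hi, unit)]
  if (is.null(drug_range)) drug_range <- list(unit = "mg", lo = 0, hi = 5000)
  if (is.null(unit_rules)) {
    unit_rules <- data.table(from_unit = c("g", "ug"),
                             to_unit = c("mg", "mg"),
                             factor = c(1000, 0.001))
  }
  if (is.null(synonyms_signals)) {
    synonyms_signals <- rbindlist(lapply(sigcat$signal_code, function(sc) {
      data.table(variant = c(tolower(sc), paste0(tolower(sc), "-ge"),
                             paste0(tolower(sc), "-mindray")),
                 canonical = sc)
    }))
  }
  if (is.null(synonyms_events)) {
    synonyms_events <- data.table(
      variant = c("induction", "incision", "fin de chirurgie", "reveil",
                  "adrenaline"),
      canonical = c("anesthesia start", "surgery start", "surgery end",
                    "anesthesia end", "epinephrine")
    )
  }
  if (is.null(groupings)) {
    groupings <- list(extracorporeal_circulation = ecc_code_set())
  }
  if (is.null(required_events)) required_events <- step_event_labels()
  structure(list(ranges = as.data.table(ranges), drug_range = drug_range,
                 unit_rules = as.data.table(unit_rules),
                 synonyms_signals = as.data.table(synonyms_signals),
                 synonyms_events = as.data.table(synonyms_events),
                 groupings = groupings, required_events = required_events),
            class = "etl_config")
}

#' @rdname etl_config
#' @param path path to a YAML file; keys mirror the `etl_config()` arguments,
#'   tabular entries given as lists of column vectors.
#' @export
read_etl_config <- function(path) {
  assert_that(file.exists(path), "no such config file: %s", p = path,
              class = "config_error")
  y <- yaml::read_yaml(path)
  as_dt <- function(x) if (is.null(x)) NULL else as.data.table(x)
  etl_config(
    ranges = as_dt(y$ranges),
    drug_range = y$drug_range,
    unit_rules = as_dt(y$unit_rules),
    synonyms_signals = as_dt(y$synonyms_signals),
    synonyms_events = as_dt(y$synonyms_events),
    groupings = if (is.null(y$groupings)) NULL else lapply(y$groupings, unlist),
    required_events = y$required_events
  )
}
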