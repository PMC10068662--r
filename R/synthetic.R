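# Synthetic source extracts: an AIMS-like export (patients, interventions,
# 30-second vitals, drug and step events), a PMSI-like export (stays, unit
# stays, ICD-10-like diagnoses, CCAM-like procedures), biology results and a
# mortality registry, together with a ground-truth log of every injected
# vital-sign excursion and every injected corruption.

#' Specify injected vital-sign excursions
#'
#' Describes, for one signal, how threshold-crossing episodes are injected by
#' [generate_bundle()]: the threshold and direction, the expected number of
#' episodes per intervention (`episode_rate`, Poisson), the excursion depth
#' beyond the threshold (uniform over `depth_range`, signal units) and the
#' episode duration (uniform over multiples of the 30 s sampling step inside
#' `duration_range`, seconds).
#'
#' @param signal_code one of `signal_catalog()$signal_code`.
#' @param threshold numeric threshold in the signal's unit.
#' @param direction `"below"` or `"above"`.
#' @param episode_rate expected episodes per intervention (>= 0).
#' @param depth_range length-2 numeric, minimum and maximum excursion depth.
#' @param duration_range length-2 numeric, seconds; both multiples of 30.
#' @return an object of class `episode_spec`.
#' @export
#' @examples
#' episode_spec("MAP", 65, "below", episode_rate = 2)
episode_spec <- function(signal_code, threshold, direction = c("below", "above"),
                         episode_rate = 1, depth_range = c(5, 15),
                         duration_range = c(120, 600)) {
  direction <- match.arg(direction)
  assert_that(signal_code %in% signal_catalog()$signal_code,
              "unknown signal_code '%s'", signal_code = signal_code)
  assert_that(is.numeric(threshold) && length(threshold) == 1,
              "threshold must be a single number")
  assert_that(episode_rate >= 0, "episode_rate must be non-negative")
  assert_that(length(depth_range) == 2 && depth_range[1] > 0 &&
                diff(depth_range) >= 0, "depth_range must be positive and ordered")
  assert_that(length(duration_range) == 2 && diff(duration_range) >= 0,
              "duration_range must be ordered")
  assert_that(all(duration_range >= SAMPLING_STEP_S),
              "episode duration must be at least one %d s sampling step",
              k = SAMPLING_STEP_S)
  assert_that(all(duration_range %% SAMPLING_STEP_S == 0),
              "duration_range values must be multiples of the %d s sampling step",
              k = SAMPLING_STEP_S)
  structure(list(signal_code = signal_code, threshold = threshold,
                 direction = direction, episode_rate = episode_rate,
                 depth_range = as.numeric(depth_range),
                 duration_range = as.numeric(duration_range)),
            class = "episode_spec")
}

empty_truth_log <- function() {
  list(
    injected_episodes = data.table(
      intervention_id = character(), signal_code = character(),
      threshold = numeric(), direction = character(),
      start_ts = as_utc(character()), end_ts = as_utc(character()),
      depth = numeric()
    ),
    injected_corruptions = data.table(
      table = character(), row_key = character(),
      corruption_kind = character(), detail = character()
    )
  )
}

#' Generate a synthetic AIMS/PMSI source bundle with ground truth
#'
#' Emits the full set of source extracts a hospital warehouse would ingest:
#' AIMS-side patients, interventions (operating-room time windows), vital-sign
#' measurements on a fixed 30 s grid, drug administrations and anesthesia /
#' surgery step events; PMSI-side hospital stays, unit stays, diagnoses and
#' procedures (day resolution); biology results; and a mortality registry.
#'
#' Vitals follow a per-signal baseline plus AR(1) noise clipped to
#' physiological bounds. For every signal named in `episode_spec`, background
#' samples are additionally kept a 2-unit guard band on the safe side of the
#' most extreme specified threshold, so that every threshold crossing in the
#' emitted series is an injected one and the truth log is exhaustive.
#' Episodes are injected as contiguous excursions strictly beyond the
#' threshold for the logged half-open window `[start_ts, end_ts)`, separated
#' from each other and from the window edges by at least two samples.
#'
#' @param n_patients number of patients (>= 1).
#' @param interventions_per_patient Poisson rate; every patient receives at
#'   least one intervention (an AIMS record only exists for patients who
#'   reached the operating room).
#' @param seed integer seed; identical arguments and seed give identical
#'   bundles, table by table.
#' @param episode_spec a single [episode_spec()] or a list of them.
#' @param start_date first possible admission date.
#' @param span_days number of days over which interventions are spread.
#' @param dropout_rate probability that a background vitals sample is dropped,
#'   creating gaps; samples inside or adjacent to injected episodes are never
#'   dropped, so logged episodes stay exactly recoverable.
#' @return a list with class `source_bundle_set`: `bundle` (named list of
#'   data.tables: patients, interventions, measurements, events, stays,
#'   unit_stays, diagnoses, procedures, biology, deaths) and `truth_log`
#'   (`injected_episodes`, `injected_corruptions`).
#' @export
#' @examples
#' gen <- generate_bundle(5, seed = 7,
#'   episode_spec = episode_spec("MAP", 65, "below", episode_rate = 1))
#' nrow(gen$truth_log$injected_episodes)
generate_bundle <- function(n_patients, interventions_per_patient = 1.2,
                            seed = 1L, episode_spec = list(),
                            start_date = as.Date("2024-03-01"),
                            span_days = 60L, dropout_rate = 0) {
  assert_that(is.numeric(n_patients) && length(n_patients) == 1 && n_patients >= 1,
              "n_patients must be a positive count")
  assert_that(interventions_per_patient > 0,
              "interventions_per_patient must be positive")
  assert_that(dropout_rate >= 0 && dropout_rate < 1,
              "dropout_rate must be in [0, 1)")
  if (inherits(episode_spec, "episode_spec")) episode_spec <- list(episode_spec)
  assert_that(all(vapply(episode_spec, inherits, TRUE, "episode_spec")),
              "episode_spec must be episode_spec objects")
  n_patients <- as.integer(n_patients)
  step <- SAMPLING_STEP_S
  set.seed(as.integer(seed))

  sigcat <- signal_catalog()

  ## ---- patients ----
  patients <- data.table(
    patient_id = sprintf("P%05d", seq_len(n_patients)),
    sex = sample(c("M", "F"), n_patients, replace = TRUE),
    birth_date = start_date - sample(20:90, n_patients, replace = TRUE) * 365L -
      sample(0:364, n_patients, replace = TRUE)
  )

  ## ---- interventions: one OR window per record, on the 30 s grid ----
  n_iv_per_pat <- pmax(1L, rpois(n_patients, interventions_per_patient))
  iv_patient <- rep(patients$patient_id, n_iv_per_pat)
  n_iv <- length(iv_patient)
  iv_day <- sample(0:(span_days - 1L), n_iv, replace = TRUE)
  entry_sec <- sample(seq(7L * 3600L, 17L * 3600L, by = step), n_iv, replace = TRUE)
  dur_sec <- sample(seq(3600L, 6L * 3600L, by = step), n_iv, replace = TRUE)
  interventions <- data.table(
    intervention_id = sprintf("I%06d", seq_len(n_iv)),
    patient_id = iv_patient,
    room_entry_ts = as_utc(as.POSIXct(start_date, tz = "UTC")) +
      iv_day * 86400 + entry_sec,
    room_exit_ts = as_utc(as.POSIXct(start_date, tz = "UTC")) +
      iv_day * 86400 + entry_sec + dur_sec,
    unit_label = sample(care_units(), n_iv, replace = TRUE)
  )

  ## ---- PMSI stays: one per intervention, day resolution ----
  adm_lag <- sample(0:2, n_iv, replace = TRUE)
  dis_lag <- sample(2:12, n_iv, replace = TRUE)
  entry_date <- as.Date(interventions$room_entry_ts, tz = "UTC")
  exit_date <- as.Date(interventions$room_exit_ts, tz = "UTC")
  stays <- data.table(
    stay_id = sprintf("S%06d", seq_len(n_iv)),
    patient_id = interventions$patient_id,
    admission_date = entry_date - adm_lag,
    discharge_date = exit_date + dis_lag,
    discharge_status = sample(c("home", "transfer", "deceased"), n_iv,
                              replace = TRUE, prob = c(0.85, 0.10, 0.05))
  )

  ## unit stays: a ward stay covering the whole stay, plus ICU for ~20%
  icu <- runif(n_iv) < 0.2
  unit_stays <- rbind(
    data.table(unit_stay_id = sprintf("U%06dA", seq_len(n_iv)),
               stay_id = stays$stay_id,
               unit_label = interventions$unit_label,
               start_date = stays$admission_date,
               end_date = stays$discharge_date),
    data.table(unit_stay_id = sprintf("U%06dB", which(icu)),
               stay_id = stays$stay_id[icu],
               unit_label = "intensive care",
               start_date = entry_date[icu],
               end_date = pmin(entry_date[icu] + sample(1:3, sum(icu), replace = TRUE),
                               stays$discharge_date[icu]))
  )

  ## diagnoses and procedures per stay
  icd <- icd10_codes(); ccam <- ccam_codes()
  n_dx <- sample(1:4, n_iv, replace = TRUE)
  diagnoses <- data.table(
    diagnosis_id = sprintf("D%06d", seq_len(sum(n_dx))),
    stay_id = rep(stays$stay_id, n_dx),
    code = sample(icd$code, sum(n_dx), replace = TRUE),
    dx_type = sample(c("principal", "associated"), sum(n_dx),
                     replace = TRUE, prob = c(0.4, 0.6))
  )
  # cardiac-surgery stays draw from the extracorporeal-circulation subset
  n_px <- sample(1:3, n_iv, replace = TRUE)
  px_stay <- rep(seq_len(n_iv), n_px)
  cardiac <- interventions$unit_label[px_stay] == "cardiac surgery"
  px_code <- character(length(px_stay))
  px_code[cardiac] <- sample(ccam[ecc == TRUE, code], sum(cardiac), replace = TRUE)
  px_code[!cardiac] <- sample(ccam[ecc == FALSE, code], sum(!cardiac), replace = TRUE)
  procedures <- data.table(
    procedure_id = sprintf("X%06d", seq_along(px_stay)),
    stay_id = stays$stay_id[px_stay],
    code = px_code,
    procedure_date = entry_date[px_stay]
  )

  ## biology: admission panel + postoperative troponin for half the stays
  biocat <- biology_catalog()
  bio_list <- vector("list", n_iv)
  for (i in seq_len(n_iv)) {
    base_ts <- as_utc(as.POSIXct(stays$admission_date[i], tz = "UTC")) + 7 * 3600
    panel <- biocat[analyte %in% c("hemoglobin", "creatinine")]
    rows <- data.table(
      stay_id = stays$stay_id[i],
      analyte = panel$analyte,
      ts = base_ts + seq_len(nrow(panel)) * 60,
      value = round(runif(nrow(panel), panel$lo, panel$hi), 1),
      unit = panel$unit
    )
    if (runif(1) < 0.5) {
      tn <- biocat[analyte == "hstnt"]
      rows <- rbind(rows, data.table(
        stay_id = stays$stay_id[i], analyte = "hstnt",
        ts = as_utc(interventions$room_exit_ts[i]) + 6 * 3600,
        value = round(runif(1, tn$lo, tn$hi), 1), unit = tn$unit))
    }
    bio_list[[i]] <- rows
  }
  biology <- rbindlist(bio_list)
  biology[, biology_id := sprintf("B%06d", .I)]
  setcolorder(biology, "biology_id")

  ## mortality registry
  # a death can only terminate the patient's chronologically last stay
  dec_pat <- unique(stays$patient_id[stays$discharge_status == "deceased"])
  if (length(dec_pat)) {
    stays[patient_id %in% dec_pat & discharge_status == "deceased",
          discharge_status := "home"]
    last_idx <- stays[patient_id %in% dec_pat,
                      .I[which.max(discharge_date)], by = patient_id]$V1
    stays[last_idx, discharge_status := "deceased"]
  }
  dead <- stays$discharge_status == "deceased"
  deaths <- if (any(dead)) {
    stays[dead, .(death_date = max(discharge_date)), by = patient_id]
  } else {
    data.table(patient_id = character(), death_date = as.Date(character()))
  }
  setorder(deaths, patient_id)

  ## ---- step + drug events ----
  drugs <- drug_catalog()
  ev_list <- vector("list", n_iv)
  for (i in seq_len(n_iv)) {
    t0 <- interventions$room_entry_ts[i]
    t1 <- interventions$room_exit_ts[i]
    dur <- as.numeric(t1 - t0, units = "secs")
    an_start <- t0 + sample(seq(60, 600, by = step), 1)
    su_start <- an_start + sample(seq(300, 1200, by = step), 1)
    an_end <- t1 - sample(seq(60, 300, by = step), 1)
    su_end <- an_end - sample(seq(300, 900, by = step), 1)
    if (su_end <= su_start) su_end <- su_start + step  # degenerate short case
    steps <- data.table(
      intervention_id = interventions$intervention_id[i],
      event_label = step_event_labels(),
      ts = as_utc(c(an_start, su_start, su_end, an_end)),
      kind = "step", dose = NA_real_, dose_unit = NA_character_
    )
    n_dr <- sample(2:5, 1)
    dri <- sample(nrow(drugs), n_dr, replace = TRUE)
    dr <- data.table(
      intervention_id = interventions$intervention_id[i],
      event_label = drugs$drug_label[dri],
      ts = t0 + sample(seq(0, max(step, dur - step), by = step), n_dr, replace = TRUE),
      kind = "drug",
      dose = round(runif(n_dr, drugs$dose_lo[dri], drugs$dose_hi[dri]), 2),
      dose_unit = drugs$dose_unit[dri]
    )
    ev_list[[i]] <- rbind(steps, dr)
  }
  events <- rbindlist(ev_list)
  events[, event_id := sprintf("E%07d", .I)]
  setcolorder(events, "event_id")

  ## ---- measurements: 30 s grid, AR(1) noise, injected excursions ----
  truth <- empty_truth_log()
  spec_by_signal <- split(episode_spec,
                          vapply(episode_spec, `[[`, "", "signal_code"))
  meas_list <- vector("list", n_iv)
  ep_list <- list()
  for (i in seq_len(n_iv)) {
    t0 <- interventions$room_entry_ts[i]
    t1 <- interventions$room_exit_ts[i]
    n_s <- as.integer(floor(as.numeric(t1 - t0, units = "secs") / step))
    ts_grid <- t0 + (seq_len(n_s) - 1L) * step
    per_sig <- vector("list", nrow(sigcat))
    for (s in seq_len(nrow(sigcat))) {
      sg <- sigcat[s]
      innov <- rnorm(n_s, 0, sg$sd * sqrt(1 - sg$ar1^2))
      x <- numeric(n_s)
      x[1] <- rnorm(1, 0, sg$sd)
      for (j in seq_len(n_s - 1L)) x[j + 1L] <- sg$ar1 * x[j] + innov[j + 1L]
      val <- pmin(pmax(sg$baseline + x, sg$lo), sg$hi)

      specs <- spec_by_signal[[sg$signal_code]]
      ep_idx <- integer(0)
      if (!is.null(specs)) {
        # guard band: background stays 2 units on the safe side of the most
        # extreme threshold per direction, so only injected samples cross
        thr_below <- suppressWarnings(max(vapply(
          Filter(function(e) e$direction == "below", specs),
          `[[`, 0, "threshold"), -Inf))
        thr_above <- suppressWarnings(min(vapply(
          Filter(function(e) e$direction == "above", specs),
          `[[`, 0, "threshold"), Inf))
        if (is.finite(thr_below)) val <- pmax(val, thr_below + 2)
        if (is.finite(thr_above)) val <- pmin(val, thr_above - 2)

        occupied <- rep(FALSE, n_s)
        for (es in specs) {
          n_ep <- rpois(1, es$episode_rate)
          if (n_ep == 0) next
          dur_opts <- seq(es$duration_range[1], es$duration_range[2], by = step)
          placed <- 0L
          for (attempt in seq_len(n_ep * 20L)) {
            if (placed >= n_ep) break
            d_len <- safe_sample(dur_opts, 1) / step          # samples in episode
            # keep a 2-sample margin from window edges and other episodes
            lo_i <- 3L
            hi_i <- n_s - d_len - 2L
            if (hi_i < lo_i) break
            s0 <- safe_sample(lo_i:hi_i, 1)
            span <- (s0 - 2L):(s0 + d_len + 1L)
            if (any(occupied[span])) next
            depth <- runif(1, es$depth_range[1], es$depth_range[2])
            exc <- depth * runif(d_len, 0.7, 1)
            exc[ceiling(d_len / 2)] <- depth           # nadir hits full depth
            idx <- s0:(s0 + d_len - 1L)
            val[idx] <- if (es$direction == "below") es$threshold - exc
                        else es$threshold + exc
            occupied[span] <- TRUE
            placed <- placed + 1L
            ep_list[[length(ep_list) + 1L]] <- data.table(
              intervention_id = interventions$intervention_id[i],
              signal_code = sg$signal_code,
              threshold = es$threshold, direction = es$direction,
              start_ts = ts_grid[s0],
              end_ts = ts_grid[s0] + d_len * step,
              depth = depth
            )
            ep_idx <- c(ep_idx, span)
          }
        }
      }

      keep <- rep(TRUE, n_s)
      if (dropout_rate > 0) {
        droppable <- setdiff(seq_len(n_s), ep_idx)
        keep[droppable] <- runif(length(droppable)) >= dropout_rate
      }
      per_sig[[s]] <- data.table(
        intervention_id = interventions$intervention_id[i],
        signal_code = sg$signal_code,
        ts = ts_grid[keep],
        value = round(val[keep], 1),
        unit_label = sg$unit
      )
    }
    meas_list[[i]] <- rbindlist(per_sig)
  }
  measurements <- rbindlist(meas_list)
  measurements[, measurement_id := sprintf("M%08d", .I)]
  setcolorder(measurements, "measurement_id")
  if (length(ep_list)) truth$injected_episodes <- rbindlist(ep_list)

  bundle <- list(
    patients = patients, interventions = interventions,
    measurements = measurements, events = events,
    stays = stays, unit_stays = unit_stays,
    diagnoses = diagnoses, procedures = procedures,
    biology = biology, deaths = deaths
  )
  structure(list(bundle = bundle, truth_log = truth),
            class = "source_bundle_set")
}

corruption_kinds <- function() {
  c("missing_id", "wrong_unit", "out_of_range",
    "misspelled_vocab", "duplicate_vocab", "date_discordance")
}

# number of rows to corrupt: value in [0,1) is a rate over eligible rows,
# value >= 1 an exact count
n_corrupt <- function(rate, n_eligible) {
  if (rate >= 1) min(as.integer(round(rate)), n_eligible)
  else as.integer(round(rate * n_eligible))
}

# mangle a label so that normalization cannot recover it (vowel dropped),
# emulating an uncorrectable manual-entry misspelling
misspell <- function(x) {
  out <- sub("([aeiou])", "", x)
  paste0(toupper(substr(out, 1, 1)), substring(out, 2))
}

#' Inject known corruptions into a source bundle
#'
#' Applies realistic source-data defects at given rates and logs every one,
#' so that downstream quality flagging and data-quality checks can be scored
#' against ground truth. Kinds: `missing_id` (measurement loses its
#' intervention id), `wrong_unit` (a drug dose in mg is re-expressed in g:
#' dose/1000, unit `"g"`), `out_of_range` (a measurement value is pushed far
#' outside the plausible range), `misspelled_vocab` (a required step-event
#' label is misspelled beyond what normalization can repair),
#' `duplicate_vocab` (a signal code gains a monitor-brand suffix, e.g.
#' `HR-GE`), `date_discordance` (a hospital stay's dates are shifted so it no
#' longer contains its operating-room date).
#'
#' Rates in `[0, 1)` are interpreted as a fraction of eligible rows; values
#' `>= 1` as an exact row count. Rows are corrupted at most once; clean rows
#' are untouched.
#'
#' @param x a `source_bundle_set` from [generate_bundle()], or a bare bundle
#'   list.
#' @param corruption_spec named numeric vector/list, names among
#'   `corruption_kinds()`.
#' @param seed integer seed.
#' @return a `source_bundle_set` whose `truth_log$injected_corruptions` lists
#'   every corrupted row as (table, row_key, corruption_kind, detail).
#' @export
#' @examples
#' gen <- generate_bundle(3, seed = 1)
#' cor <- corrupt_bundle(gen, c(missing_id = 2, wrong_unit = 2), seed = 2)
#' cor$truth_log$injected_corruptions
corrupt_bundle <- function(x, corruption_spec, seed = 1L) {
  if (inherits(x, "source_bundle_set")) {
    bundle <- x$bundle; truth <- x$truth_log
  } else {
    bundle <- x; truth <- empty_truth_log()
  }
  spec <- as.list(corruption_spec)
  unknown <- setdiff(names(spec), corruption_kinds())
  assert_that(length(unknown) == 0, "unknown corruption kind(s): %s",
              k = paste(unknown, collapse = ", "))
  assert_that(all(unlist(spec) >= 0), "corruption rates must be non-negative")
  set.seed(as.integer(seed))

  bundle <- lapply(bundle, copy)
  log_rows <- list()
  add_log <- function(table, keys, kind, detail) {
    log_rows[[length(log_rows) + 1L]] <<- data.table(
      table = table, row_key = keys, corruption_kind = kind,
      detail = as.character(detail))
  }
  used_meas <- character(0)  # measurement ids already corrupted

  for (kind in names(spec)) {
    rate <- spec[[kind]]
    if (rate == 0) next
    if (kind == "missing_id") {
      elig <- setdiff(bundle$measurements$measurement_id, used_meas)
      n <- n_corrupt(rate, length(elig))
      if (n == 0) next
      keys <- sample(elig, n)
      used_meas <- c(used_meas, keys)
      orig <- bundle$measurements[measurement_id %in% keys,
                                  setNames(intervention_id, measurement_id)]
      bundle$measurements[measurement_id %in% keys, intervention_id := NA_character_]
      add_log("measurements", keys, kind, orig[keys])
    } else if (kind == "wrong_unit") {
      elig <- bundle$events[kind == "drug" & dose_unit == "mg", event_id,
                            env = list(kind = "kind")]
      n <- n_corrupt(rate, length(elig))
      if (n == 0) next
      keys <- sample(elig, n)
      orig <- bundle$events[event_id %in% keys, setNames(dose, event_id)]
      bundle$events[event_id %in% keys,
                    `:=`(dose = dose / 1000, dose_unit = "g")]
      add_log("events", keys, kind, orig[keys])
    } else if (kind == "out_of_range") {
      elig <- setdiff(bundle$measurements$measurement_id, used_meas)
      n <- n_corrupt(rate, length(elig))
      if (n == 0) next
      keys <- sample(elig, n)
      used_meas <- c(used_meas, keys)
      sigcat <- signal_catalog()[, .(signal_code, hi)]
      tgt <- bundle$measurements[measurement_id %in% keys]
      tgt <- merge(tgt, sigcat, by = "signal_code", sort = FALSE)
      orig <- setNames(tgt$value, tgt$measurement_id)
      newv <- setNames(round(tgt$hi * 1.5 + 100, 1), tgt$measurement_id)
      bundle$measurements[measurement_id %in% keys,
                          value := newv[measurement_id]]
      add_log("measurements", names(orig), kind, orig)
    } else if (kind == "misspelled_vocab") {
      elig <- bundle$events[kind == "step" & event_label %in% step_event_labels(),
                            event_id, env = list(kind = "kind")]
      n <- n_corrupt(rate, length(elig))
      if (n == 0) next
      keys <- sample(elig, n)
      orig <- bundle$events[event_id %in% keys, setNames(event_label, event_id)]
      bundle$events[event_id %in% keys, event_label := misspell(event_label)]
      add_log("events", keys, kind, orig[keys])
    } else if (kind == "duplicate_vocab") {
      elig <- setdiff(bundle$measurements$measurement_id, used_meas)
      n <- n_corrupt(rate, length(elig))
      if (n == 0) next
      keys <- sample(elig, n)
      used_meas <- c(used_meas, keys)
      orig <- bundle$measurements[measurement_id %in% keys,
                                  setNames(signal_code, measurement_id)]
      brand <- sample(c("-GE", "-Mindray"), n, replace = TRUE)
      bundle$measurements[measurement_id %in% keys,
                          signal_code := paste0(signal_code,
                                                brand[match(measurement_id, keys)])]
      add_log("measurements", keys, kind, orig[keys])
    } else if (kind == "date_discordance") {
      # only stays whose intervention date is not covered by a sibling stay,
      # so the discordance is guaranteed detectable
      iv <- bundle$interventions[!is.na(patient_id)]
      iv[, or_date := as.Date(room_entry_ts, tz = "UTC")]
      st <- bundle$stays
      cand <- merge(iv[, .(intervention_id, patient_id, or_date)],
                    st[, .(stay_id, patient_id, admission_date, discharge_date)],
                    by = "patient_id", allow.cartesian = TRUE)
      cand <- cand[or_date >= admission_date & or_date <= discharge_date]
      n_cover <- cand[, .N, by = intervention_id]
      # stays that are the unique cover of some intervention
      uniq_iv <- n_cover[N == 1, intervention_id]
      elig <- unique(cand[intervention_id %in% uniq_iv, stay_id])
      n <- n_corrupt(rate, length(elig))
      if (n == 0) next
      keys <- sample(elig, n)
      orig <- st[stay_id %in% keys, setNames(fmt_date(admission_date), stay_id)]
      bundle$stays[stay_id %in% keys,
                   `:=`(admission_date = admission_date + 400L,
                        discharge_date = discharge_date + 400L)]
      add_log("stays", keys, kind, orig[keys])
    }
  }

  if (length(log_rows)) {
    truth$injected_corruptions <- rbind(truth$injected_corruptions,
                                        rbindlist(log_rows))
  }
  structure(list(bundle = bundle, truth_log = truth),
            class = "source_bundle_set")
}

bundle_table_names <- function() {
  c("patients", "interventions", "measurements", "events", "stays",
    "unit_stays", "diagnoses", "procedures", "biology", "deaths")
}

# columns serialized as ISO-8601 timestamps / dates per table
ts_columns <- function() {
  list(interventions = c("room_entry_ts", "room_exit_ts"),
       measurements = "ts", events = "ts", biology = "ts")
}
date_columns <- function() {
  list(patients = "birth_date",
       stays = c("admission_date", "discharge_date"),
       unit_stays = c("start_date", "end_date"),
       procedures = "procedure_date",
       deaths = "death_date")
}

#' Write / read a source bundle as delimited UTF-8 files
#'
#' One tab-separated file per table with ISO-8601 timestamps, plus
#' `truth_log.json`. The on-disk form is byte-deterministic for a fixed
#' bundle, so mirrored snapshots can be compared by checksum.
#'
#' @param x a `source_bundle_set` (or bare bundle list).
#' @param dir output directory, created if needed.
#' @return `write_bundle()`: `dir`, invisibly. `read_bundle()`: a
#'   `source_bundle_set`.
#' @export
write_bundle <- function(x, dir) {
  if (inherits(x, "source_bundle_set")) {
    bundle <- x$bundle; truth <- x$truth_log
  } else {
    bundle <- x; truth <- NULL
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsc <- ts_columns(); dtc <- date_columns()
  for (nm in names(bundle)) {
    dt <- copy(bundle[[nm]])
    for (cc in intersect(tsc[[nm]] %||% character(0), names(dt)))
      set(dt, j = cc, value = fmt_ts(dt[[cc]]))
    for (cc in intersect(dtc[[nm]] %||% character(0), names(dt)))
      set(dt, j = cc, value = fmt_date(dt[[cc]]))
    fwrite(dt, file.path(dir, paste0(nm, ".tsv")), sep = "\t", quote = FALSE)
  }
  if (!is.null(truth)) {
    tl <- list(
      injected_episodes = {
        ep <- copy(truth$injected_episodes)
        ep[, `:=`(start_ts = fmt_ts(start_ts), end_ts = fmt_ts(end_ts))]
        ep
      },
      injected_corruptions = truth$injected_corruptions
    )
    jsonlite::write_json(tl, file.path(dir, "truth_log.json"),
                         dataframe = "rows", na = "null", digits = NA)
  }
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  assert_that(dir.exists(dir), "no such directory: %s", d = dir,
              class = "load_error")
  tsc <- ts_columns(); dtc <- date_columns()
  bundle <- list()
  for (nm in bundle_table_names()) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    assert_that(file.exists(f), "missing source file: %s", f = f,
                class = "load_error")
    dt <- fread(f, sep = "\t", colClasses = list(character = 1:2), na.strings = "")
    for (cc in intersect(tsc[[nm]] %||% character(0), names(dt))) {
      parsed <- if (inherits(dt[[cc]], "POSIXct")) as_utc(dt[[cc]])
                else parse_ts(as.character(dt[[cc]]))
      bad <- which(!is.na(dt[[cc]]) & is.na(parsed))
      assert_that(length(bad) == 0,
                  "malformed timestamp in %s, column %s, row %d",
                  class = "load_error", nm, cc,
                  if (length(bad)) bad[1] else 0L)
      set(dt, j = cc, value = parsed)
    }
    for (cc in intersect(dtc[[nm]] %||% character(0), names(dt)))
      set(dt, j = cc, value = as.Date(dt[[cc]]))
    bundle[[nm]] <- dt
  }
  truth <- empty_truth_log()
  tf <- file.path(dir, "truth_log.json")
  if (file.exists(tf)) {
    tl <- jsonlite::read_json(tf, simplifyVector = TRUE)
    if (length(tl$injected_episodes)) {
      ep <- as.data.table(tl$injected_episodes)
      ep[, `:=`(start_ts = parse_ts(start_ts), end_ts = parse_ts(end_ts))]
      truth$injected_episodes <- ep
    }
    if (length(tl$injected_corruptions))
      truth$injected_corruptions <- as.data.table(tl$injected_corruptions)
  }
  structure(list(bundle = bundle, truth_log = truth),
            class = "source_bundle_set")
}

#' @export
print.source_bundle_set <- function(x, ...) {
  cat("<source_bundle_set>\n")
  for (nm in names(x$bundle))
    cat(sprintf("  %-14s %6d rows\n", nm, nrow(x$bundle[[nm]])))
  cat(sprintf("  injected episodes:    %d\n", nrow(x$truth_log$injected_episodes)))
  cat(sprintf("  injected corruptions: %d\n", nrow(x$truth_log$injected_corruptions)))
  invisible(x)
}
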