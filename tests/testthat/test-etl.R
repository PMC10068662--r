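# Mirroring, transform primitives (linkage, vocabulary, units, quality
# flags, code grouping) and the two incremental load flows.

test_that("mirroring copies sources faithfully and is idempotent", {
  g <- generate_bundle(3, seed = 31)
  src <- tempfile(); s1 <- tempfile(); s2 <- tempfile()
  write_bundle(g, src)
  m1 <- mirror(src, s1)
  for (nm in names(g$bundle))
    expect_identical(nrow(m1$bundle[[nm]]), nrow(g$bundle[[nm]]))
  mirror(src, s2)
  for (f in list.files(s1))
    expect_identical(unname(tools::md5sum(file.path(s1, f))),
                     unname(tools::md5sum(file.path(s2, f))))
  # originals untouched
  expect_identical(unname(tools::md5sum(file.path(src, "measurements.tsv"))),
                   unname(tools::md5sum(file.path(s1, "measurements.tsv"))))
})

test_that("a malformed timestamp is rejected with file and row", {
  g <- generate_bundle(2, seed = 31)
  src <- tempfile()
  write_bundle(g, src)
  f <- file.path(src, "interventions.tsv")
  lines <- readLines(f)
  lines[2] <- sub("T\\d\\d:", "Tzz:", lines[2])
  writeLines(lines, f)
  err <- tryCatch(read_bundle(src), error = identity)
  expect_s3_class(err, "load_error")
  expect_match(conditionMessage(err), "interventions")
  expect_match(conditionMessage(err), "row 1")
})

test_that("linkage picks the containing stay with the latest admission", {
  iv <- data.table(
    intervention_id = c("I1", "I2", "I3"),
    patient_id = c("P1", "P2", NA),
    room_entry_ts = as.POSIXct(c("2024-01-05 09:00:00", "2024-01-05 10:00:00",
                                 "2024-01-05 11:00:00"), tz = "UTC"))
  stays <- data.table(
    stay_id = c("S1", "S2a", "S2b"),
    patient_id = c("P1", "P2", "P2"),
    admission_date = as.Date(c("2024-01-01", "2024-01-01", "2024-01-04")),
    discharge_date = as.Date(c("2024-01-10", "2024-01-10", "2024-01-10")))
  lk <- link_records(iv, stays)
  # unique containing stay
  expect_identical(lk$links[intervention_id == "I1", stay_id], "S1")
  # two candidates: the day-4 admission wins over day-1 (smallest gap)
  expect_identical(lk$links[intervention_id == "I2", stay_id], "S2b")
  # null patient id is reported, not dropped
  expect_identical(lk$unlinked[intervention_id == "I3", reason],
                   "missing_patient_id")
})

test_that("interventions outside any stay are unlinked with no_candidate", {
  iv <- data.table(intervention_id = "I1", patient_id = "P1",
                   room_entry_ts = as.POSIXct("2024-06-01 09:00:00", tz = "UTC"))
  stays <- data.table(stay_id = "S1", patient_id = "P1",
                      admission_date = as.Date("2024-01-01"),
                      discharge_date = as.Date("2024-01-10"))
  lk <- link_records(iv, stays)
  expect_identical(nrow(lk$links), 0L)
  expect_identical(lk$unlinked$reason, "no_candidate")
})

test_that("vocabulary cleaning normalizes and collapses brand synonyms", {
  m <- clean_vocabulary(c("Heart  Rate ", "heart rate"))
  expect_identical(unique(m$canonical), "heart rate")
  syn <- data.table(variant = c("HR-GE", "HR-Mindray"),
                    canonical = c("heart rate", "heart rate"))
  m2 <- clean_vocabulary(c("HR-GE", "hr-mindray"), syn)
  expect_identical(unique(m2$canonical), "heart rate")
  # unmapped labels become their own normalized canonical form
  m3 <- clean_vocabulary("SpO2")
  expect_identical(m3$canonical, "spo2")
  # one variant, two canonicals is a configuration error
  bad <- data.table(variant = c("x", "X"), canonical = c("a", "b"))
  expect_error(clean_vocabulary("x", bad), class = "config_error")
})

test_that("unit conversion applies single-step rules and flags nothing itself", {
  rules <- data.table(from_unit = "g", to_unit = "mg", factor = 1000)
  out <- convert_units(data.table(value = 1, unit_label = "g"), rules)
  expect_identical(out$value, 1000)
  expect_identical(out$unit_label, "mg")
  out2 <- convert_units(data.table(value = 250, unit_label = "mg"), rules)
  expect_identical(out2$value, 250)
  out3 <- convert_units(data.table(value = 5, unit_label = "furlongs"), rules)
  expect_identical(out3$unit_label, "furlongs")  # left for quality flagging
  expect_error(convert_units(out, data.table(from_unit = c("g", "g"),
                                             to_unit = c("mg", "kg"),
                                             factor = c(1000, 0.001))),
               class = "config_error")
  expect_error(convert_units(out, data.table(from_unit = c("g", "mg"),
                                             to_unit = c("mg", "g"),
                                             factor = c(1000, 0.001))),
               class = "config_error")
})

test_that("code grouping flags exactly the stays with in-set procedures", {
  px <- data.table(stay_id = sprintf("S%02d", rep(1:10, each = 2)),
                   code = "NEKA020")
  in_set <- ecc_code_set()
  px[stay_id %in% c("S03", "S07", "S10"), code := in_set[1]]
  grp <- group_codes(px, list(name = "ecc", codes = in_set))
  expect_identical(grp[ecc == TRUE, stay_id], c("S03", "S07", "S10"))
  expect_identical(sum(grp$ecc), 3L)
  expect_error(group_codes(px, list(name = "ecc", codes = character())),
               class = "config_error")
})

test_that("quality flags follow the documented precedence", {
  rt <- data.table(signal_code = c("HR", "MAP"), lo = c(20, 30),
                   hi = c(250, 150), unit = c("bpm", "mmHg"))
  ms <- data.table(
    measurement_id = sprintf("M%d", 1:5),
    intervention_id = c("I1", "I1", NA, "I1", "I1"),
    signal_code = c("HR", "MAP", "HR", "HR", "MAP"),
    value = c(400, 80, 75, NA, 90),
    unit_label = c("bpm", "mmHg", "bpm", "bpm", "kPa"))
  fl <- flag_quality(ms, rt)
  expect_identical(fl$quality_flag,
                   c("out_of_range", "ok", "orphan", "missing_value",
                     "bad_unit"))
  expect_error(flag_quality(data.table(measurement_id = "M9",
                                       intervention_id = "I1",
                                       signal_code = "EEG", value = 1,
                                       unit_label = "x"), rt),
               class = "config_error")
})

test_that("flow 1 reflects source updates and ignores out-of-window rows", {
  g <- generate_bundle(4, seed = 33)
  cfg <- etl_config()
  stg <- transform_staging(g, cfg)
  as_of <- max(g$bundle$stays$discharge_date) + 1
  wh <- load_flow1(wh_init(cfg), stg, as_of)
  expect_identical(nrow(wh$tables$hospital_stay), nrow(g$bundle$stays))

  # update a discharge date in the source; reload reflects it
  g2 <- list(bundle = lapply(g$bundle, data.table::copy),
             truth_log = g$truth_log)
  class(g2) <- "source_bundle_set"
  sid <- g2$bundle$stays$stay_id[1]
  g2$bundle$stays[stay_id == sid, discharge_date := discharge_date + 5L]
  wh2 <- load_flow1(wh, transform_staging(g2, cfg), as_of)
  expect_identical(wh2$tables$hospital_stay[stay_id == sid, discharge_date],
                   g2$bundle$stays[stay_id == sid, discharge_date])

  # a run whose window is empty loads nothing and changes nothing
  wh3 <- load_flow1(wh2, transform_staging(g2, cfg), as_of + 800)
  log <- wh3$tables$load_log[.N]
  expect_identical(log$rows_loaded, 0L)
  expect_identical(wh_checksum(wh3), wh_checksum(wh2))
})

test_that("flow 2 honors its 14-day window and weekly runs tile without gaps", {
  g <- generate_bundle(4, seed = 34)
  stg <- transform_staging(g)
  or_dates <- as.Date(g$bundle$interventions$room_entry_ts, tz = "UTC")

  # measurements older than 14 days are not loaded
  wh <- load_flow2(wh_init(), stg, max(or_dates) + 20)
  expect_identical(nrow(wh$tables$measurement), 0L)

  # consecutive weekly runs: no duplicates, no gaps over the covered span
  wh <- wh_init()
  for (d in as.list(seq(min(or_dates) + 13, max(or_dates) + 14, by = 7)))
    wh <- load_flow2(wh, stg, d)
  expect_identical(anyDuplicated(wh$tables$measurement$measurement_id), 0L)
  expect_setequal(wh$tables$measurement$measurement_id,
                  stg$tables$measurements$measurement_id)
  expect_setequal(wh$tables$intervention$intervention_id,
                  stg$tables$interventions$intervention_id)
})

test_that("load flows are idempotent and conserve row counts", {
  wh <- fix_clean_wh()
  g <- fix_clean_gen()
  stg <- transform_staging(g)
  ck <- wh_checksum(wh)
  wh2 <- load_flow1(wh, stg, max(g$bundle$stays$discharge_date) + 1)
  last_d <- max(as.Date(g$bundle$interventions$room_entry_ts, tz = "UTC")) + 14
  wh2 <- load_flow2(wh2, stg, last_d)
  expect_identical(wh_checksum(wh2), ck)
  log <- wh2$tables$load_log
  expect_true(all(log$rows_in == log$rows_loaded + log$rows_rejected))
  expect_true(all(log$status == "ok"))
})

test_that("orphaned measurements are quarantined, never loaded", {
  g <- corrupt_bundle(generate_bundle(3, seed = 35), c(missing_id = 4), seed = 1)
  wh <- load_full(g)
  orphans <- g$truth_log$injected_corruptions$row_key
  expect_false(any(orphans %in% wh$tables$measurement$measurement_id))
  q <- wh$tables$quarantine
  expect_setequal(q[table == "measurement", row_key], orphans)
  # referential integrity: every loaded ok measurement has its intervention
  ok_ms <- wh$tables$measurement[quality_flag == "ok"]
  expect_true(all(ok_ms$intervention_id %in%
                    wh$tables$intervention$intervention_id))
})

test_that("a run cannot start while another is flagged as running", {
  g <- generate_bundle(2, seed = 36)
  stg <- transform_staging(g)
  wh <- wh_init()
  wh$tables$load_log <- data.table(
    run_id = 1L, flow_id = 1L, started_ts = as.POSIXct(Sys.time(), tz = "UTC"),
    finished_ts = as.POSIXct(NA, tz = "UTC"), rows_in = 0L, rows_loaded = 0L,
    rows_rejected = 0L, window_start = Sys.Date(), window_end = Sys.Date(),
    status = "running", messages = "")
  expect_error(load_flow1(wh, stg, Sys.Date()), class = "run_rejected")
})

test_that("yaml configuration round-trips through read_etl_config", {
  cfg <- etl_config()
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    ranges = as.list(cfg$ranges),
    drug_range = cfg$drug_range,
    unit_rules = as.list(cfg$unit_rules),
    required_events = cfg$required_events), path)
  cfg2 <- read_etl_config(path)
  expect_equal(as.data.frame(cfg2$ranges), as.data.frame(cfg$ranges))
  expect_identical(cfg2$required_events, cfg$required_events)
  # unspecified keys fall back to defaults
  expect_identical(cfg2$groupings, cfg$groupings)
})
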