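# Synthetic source generator: determinism, injected-episode realizability,
# corruption logging and conservation.

test_that("generation is deterministic and schema-complete", {
  g1 <- generate_bundle(4, seed = 7)
  g2 <- generate_bundle(4, seed = 7)
  expect_identical(g1, g2)
  expect_setequal(names(g1$bundle),
                  c("patients", "interventions", "measurements", "events",
                    "stays", "unit_stays", "diagnoses", "procedures",
                    "biology", "deaths"))
  # invariants: windows ordered, samples inside them, referential integrity
  iv <- g1$bundle$interventions
  expect_true(all(iv$room_entry_ts < iv$room_exit_ts))
  expect_true(all(iv$patient_id %in% g1$bundle$patients$patient_id))
  ms <- merge(g1$bundle$measurements, iv, by = "intervention_id")
  expect_true(all(ms$ts >= ms$room_entry_ts & ms$ts < ms$room_exit_ts))
})

test_that("without an episode spec vitals stay in a baseline band", {
  g <- generate_bundle(1, interventions_per_patient = 1, seed = 7)
  expect_identical(nrow(g$truth_log$injected_episodes), 0L)
  sigcat <- signal_catalog()
  ms <- merge(g$bundle$measurements, sigcat, by = "signal_code")
  expect_true(all(ms$value >= ms$lo & ms$value <= ms$hi))
  # AR(1) noise keeps values within a few SDs of baseline
  expect_true(all(abs(ms$value - ms$baseline) <= 6 * ms$sd))
})

test_that("a 5-minute injected MAP<65 episode is ten consecutive sub-threshold samples", {
  g <- generate_bundle(3, seed = 21,
                       episode_spec = episode_spec("MAP", 65, "below",
                                                   episode_rate = 1,
                                                   duration_range = c(300, 300)))
  tl <- g$truth_log$injected_episodes
  expect_gt(nrow(tl), 0)
  ms <- g$bundle$measurements[signal_code == "MAP"]
  for (i in seq_len(nrow(tl))) {
    ep <- tl[i]
    expect_identical(as.numeric(ep$end_ts - ep$start_ts, units = "secs"), 300)
    inw <- ms[intervention_id == ep$intervention_id &
                ts >= ep$start_ts & ts < ep$end_ts]
    expect_identical(nrow(inw), 10L)  # direct scan of the emitted table
    expect_true(all(inw$value < 65))
    # samples bracketing the window are on the safe side
    expect_true(ms[intervention_id == ep$intervention_id &
                     ts == ep$start_ts - 30, value] >= 65)
    expect_true(ms[intervention_id == ep$intervention_id &
                     ts == ep$end_ts, value] >= 65)
  }
})

test_that("episode realizability holds for every logged episode", {
  g <- fix_clean_gen()
  tl <- g$truth_log$injected_episodes
  ms <- g$bundle$measurements
  for (i in seq_len(nrow(tl))) {
    ep <- tl[i]
    inw <- ms[intervention_id == ep$intervention_id &
                signal_code == ep$signal_code &
                ts >= ep$start_ts & ts < ep$end_ts]
    expect_gt(nrow(inw), 0)
    expect_true(all(if (ep$direction == "below") inw$value < ep$threshold
                    else inw$value > ep$threshold))
  }
})

test_that("episode specs reject durations off the sampling grid", {
  expect_error(episode_spec("MAP", 65, "below", duration_range = c(45, 90)),
               class = "invalid_argument")
  expect_error(episode_spec("MAP", 65, "below", duration_range = c(0, 0)),
               class = "invalid_argument")
  expect_error(generate_bundle(0, seed = 1), class = "invalid_argument")
})

test_that("zero corruption rates return the input unchanged with an empty log", {
  g <- generate_bundle(3, seed = 5)
  c0 <- corrupt_bundle(g, c(missing_id = 0, wrong_unit = 0), seed = 1)
  expect_identical(c0$bundle, g$bundle)
  expect_identical(nrow(c0$truth_log$injected_corruptions), 0L)
})

test_that("wrong_unit re-expresses exactly the logged drug rows in grams", {
  g <- generate_bundle(4, seed = 5)
  cb <- corrupt_bundle(g, c(wrong_unit = 3), seed = 2)
  log <- cb$truth_log$injected_corruptions
  expect_identical(nrow(log), 3L)
  expect_true(all(log$corruption_kind == "wrong_unit"))
  # value x 1000 recovers the original dose; unit is now g
  hit <- merge(cb$bundle$events, log, by.x = "event_id", by.y = "row_key")
  expect_true(all(hit$dose_unit == "g"))
  expect_equal(hit$dose * 1000, as.numeric(hit$detail), tolerance = 1e-12)
  # clean rows untouched
  clean <- cb$bundle$events[!event_id %in% log$row_key]
  orig <- g$bundle$events[!event_id %in% log$row_key]
  expect_identical(clean, orig)
})

test_that("missing_id nulls the logged measurement rows only", {
  g <- generate_bundle(3, seed = 5)
  cb <- corrupt_bundle(g, c(missing_id = 2), seed = 3)
  log <- cb$truth_log$injected_corruptions
  expect_identical(nrow(log), 2L)
  hit <- cb$bundle$measurements[measurement_id %in% log$row_key]
  expect_true(all(is.na(hit$intervention_id)))
  n_na <- sum(is.na(cb$bundle$measurements$intervention_id))
  expect_identical(n_na, 2L)
})

test_that("corruption conservation: clean plus logged rows equals total, per table", {
  g <- generate_bundle(5, seed = 13)
  spec <- c(missing_id = 4, wrong_unit = 2, out_of_range = 3,
            misspelled_vocab = 2, duplicate_vocab = 3, date_discordance = 1)
  cb <- corrupt_bundle(g, spec, seed = 4)
  log <- cb$truth_log$injected_corruptions
  expect_identical(nrow(log), sum(spec) |> as.integer())
  # each corrupted row is corrupted once; every named row exists
  expect_identical(anyDuplicated(log[, .(table, row_key)]), 0L)
  key_col <- c(measurements = "measurement_id", events = "event_id",
               stays = "stay_id")
  for (tab in unique(log$table)) {
    keys <- log[table == tab, row_key]
    expect_true(all(keys %in% cb$bundle[[tab]][[key_col[tab]]]))
    n_clean <- sum(!cb$bundle[[tab]][[key_col[tab]]] %in% keys)
    expect_identical(n_clean + length(keys), nrow(cb$bundle[[tab]]))
  }
})

test_that("unknown corruption kinds are rejected", {
  g <- generate_bundle(2, seed = 1)
  expect_error(corrupt_bundle(g, c(scrambled = 0.5), seed = 1),
               class = "invalid_argument")
})

test_that("bundles round-trip through delimited files byte-identically", {
  g <- corrupt_bundle(generate_bundle(3, seed = 9,
                                      episode_spec = episode_spec("MAP", 65, "below")),
                      c(missing_id = 2, wrong_unit = 1), seed = 2)
  d1 <- tempfile(); d2 <- tempfile()
  write_bundle(g, d1)
  rb <- read_bundle(d1)
  for (nm in names(g$bundle))
    expect_equal(as.data.frame(rb$bundle[[nm]]), as.data.frame(g$bundle[[nm]]),
                 ignore_attr = TRUE)
  expect_equal(nrow(rb$truth_log$injected_corruptions), 3)
  # re-writing the parsed copy reproduces the same bytes
  write_bundle(rb, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d2, f))),
                     unname(tools::md5sum(file.path(d1, f))))
  }
})
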