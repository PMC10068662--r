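# Period definition, summary statistics, threshold-episode detection under
# the LOCF step model, and long-form feature extraction.

events_one_iv <- function() {
  data.table(event_label = c("anesthesia start", "anesthesia end"),
             ts = as.POSIXct(c("2024-03-01 09:00:00", "2024-03-01 10:00:00"),
                             tz = "UTC"))
}

test_that("periods are anchored half-open intervals with offsets", {
  per <- define_period(events_one_iv(),
                       period_rule("p", "anesthesia start", 0,
                                   "anesthesia end", 0))
  expect_identical(format(per$start_ts, "%H:%M"), "09:00")
  expect_identical(format(per$end_ts, "%H:%M"), "10:00")
  per2 <- define_period(events_one_iv(),
                        period_rule("p", "anesthesia start", 300,
                                    "anesthesia end", -300))
  expect_identical(format(per2$start_ts, "%H:%M"), "09:05")
  expect_identical(format(per2$end_ts, "%H:%M"), "09:55")
})

test_that("missing, duplicated or inverted anchors are typed errors", {
  ev <- events_one_iv()
  expect_error(define_period(ev, period_rule("p", "surgery start", 0,
                                             "anesthesia end", 0)),
               class = "period_undefined")
  dup <- rbind(ev, ev[1])
  err <- tryCatch(define_period(dup, period_rule("p", "anesthesia start", 0,
                                                 "anesthesia end", 0)),
                  error = identity)
  expect_s3_class(err, "period_undefined")
  expect_match(conditionMessage(err), "09:00:00")  # lists the timestamps
  expect_error(define_period(ev, period_rule("p", "anesthesia end", 0,
                                             "anesthesia start", 0)),
               class = "invalid_period")
})

test_that("summary statistics use only ok samples inside the period", {
  per <- make_period("2024-03-01 09:00:00", "2024-03-01 10:00:00")
  one <- grid_series(80, t0 = "2024-03-01 09:10:00")
  sm <- summarize_period(one, per)
  expect_identical(sm[c("count", "min", "max", "mean", "median")],
                   list(count = 1L, min = 80, max = 80, mean = 80, median = 80))
  sm2 <- summarize_period(grid_series(c(1, 2, 3, 4), t0 = "2024-03-01 09:00:00"),
                          per)
  expect_identical(sm2$mean, 2.5)
  expect_identical(sm2$median, 2.5)
  # flagged samples and out-of-period samples do not count
  s <- grid_series(rep(70, 10), t0 = "2024-03-01 08:58:00")
  s[, quality_flag := "ok"]
  s[1:3, quality_flag := "out_of_range"]
  sm3 <- summarize_period(s, per)
  expect_identical(sm3$count, sum(s$quality_flag == "ok" &
                                    s$ts >= per$start_ts & s$ts < per$end_ts))
  # zero usable samples: count 0, statistics null, no error
  sm4 <- summarize_period(grid_series(numeric(0)), per)
  expect_identical(sm4$count, 0L)
  expect_true(is.na(sm4$mean))
})

test_that("the worked rectangle-sum example is reproduced exactly", {
  per <- make_period("2024-03-01 09:00:00", "2024-03-01 09:02:30")
  s <- grid_series(c(70, 60, 55, 60, 70))
  eps <- detect_episodes(s, per, 65, "below", min_duration_s = 0,
                         max_gap_s = 60)
  expect_identical(nrow(eps), 1L)
  expect_identical(eps$duration_s, 90)
  expect_identical(eps$area, (5 + 10 + 5) * 30)  # 600 unit-seconds
  expect_identical(eps$deepest_value, 55)
  # never crossed: no episodes
  none <- detect_episodes(grid_series(rep(80, 5)), per, 65, "below",
                          min_duration_s = 0, max_gap_s = 60)
  expect_identical(nrow(none), 0L)
  # a single 30 s dip is discarded under min_duration 60
  dip <- grid_series(c(70, 60, 70, 70, 70))
  expect_identical(nrow(detect_episodes(dip, per, 65, "below",
                                        min_duration_s = 60, max_gap_s = 60)),
                   0L)
  expect_identical(nrow(detect_episodes(dip, per, 65, "below",
                                        min_duration_s = 0, max_gap_s = 60)),
                   1L)
})

test_that("gaps longer than max_gap split episodes instead of bridging them", {
  per <- make_period("2024-03-01 09:00:00", "2024-03-01 09:30:00")
  t0 <- as.POSIXct("2024-03-01 09:00:00", tz = "UTC")
  s <- data.table(ts = t0 + c(0, 30, 60, 600, 630),  # 9-minute silence
                  value = c(60, 60, 60, 60, 70))
  eps <- detect_episodes(s, per, 65, "below", min_duration_s = 0,
                         max_gap_s = 120)
  expect_identical(nrow(eps), 2L)
  # first run: held 30+30+120 (gap capped), second: 30
  expect_identical(eps$duration_s, c(180, 30))
  # with a generous max_gap the hold bridges the silence into one episode
  eps2 <- detect_episodes(s, per, 65, "below", min_duration_s = 0,
                          max_gap_s = 600)
  expect_identical(nrow(eps2), 1L)
})

test_that("detection agrees exactly with the per-second brute-force oracle", {
  set.seed(91)
  per <- make_period("2024-03-01 09:00:00", "2024-03-01 11:00:00")
  for (case in 1:25) {
    n <- 240
    v <- 75 + cumsum(rnorm(n, 0, 4))
    v <- pmin(pmax(v, 40), 110)
    s <- grid_series(v)
    if (case %% 3 == 0) s <- s[-sample(2:(n - 1), 25)]  # ragged sampling
    thr <- sample(50:80, 1)
    mind <- sample(c(0, 60, 120), 1)
    eps <- detect_episodes(s, per, thr, "below", min_duration_s = mind,
                           max_gap_s = 300)
    bf <- brute_force_episodes(s, per, thr, "below", min_duration_s = mind,
                               max_gap_s = 300)
    expect_identical(nrow(eps), nrow(bf))
    if (nrow(eps)) {
      expect_equal(eps$duration_s, bf$duration_s)
      expect_equal(eps$area, bf$area, tolerance = 1e-12)
      expect_equal(as.numeric(eps$start_ts), bf$start_s)
    }
  }
})

test_that("episode aggregates sum durations and areas and track the nadir", {
  expect_identical(episode_features(data.table()),
                   list(n_episodes = 0L, total_time_s = 0, total_area = 0,
                        deepest_value = NA_real_))
  eps <- data.table(duration_s = c(60, 120), area = c(100, 300),
                    deepest_value = c(58, 52), threshold = 65,
                    direction = "below")
  agg <- episode_features(eps)
  expect_identical(agg$n_episodes, 2L)
  expect_identical(agg$total_time_s, 180)
  expect_identical(agg$total_area, 400)
  expect_identical(agg$deepest_value, 52)
  mixed <- copy(eps)[1, threshold := 50]
  expect_error(episode_features(mixed), class = "invalid_argument")
})

test_that("threshold monotonicity holds on randomized series", {
  set.seed(92)
  per <- make_period("2024-03-01 09:00:00", "2024-03-01 10:40:00")
  for (case in 1:30) {
    v <- pmin(pmax(70 + cumsum(rnorm(200, 0, 5)), 35), 115)
    s <- grid_series(v)
    tt <- sort(runif(2, 50, 80))
    a1 <- episode_features(detect_episodes(s, per, tt[1], "below",
                                           min_duration_s = 0))
    a2 <- episode_features(detect_episodes(s, per, tt[2], "below",
                                           min_duration_s = 0))
    expect_lte(a1$total_time_s, a2$total_time_s)
    expect_lte(a1$total_area, a2$total_area)
    # bounds: time within the period, min-duration lower bound on time
    per_len <- as.numeric(per$end_ts - per$start_ts, units = "secs")
    expect_lte(a2$total_time_s, per_len)
    b <- episode_features(detect_episodes(s, per, tt[2], "below",
                                          min_duration_s = 90))
    expect_lte(b$n_episodes * 90, max(b$total_time_s, 0) + 1e-9)
  }
})

test_that("injected episodes are recovered exactly from the warehouse", {
  g <- fix_clean_gen()
  wh <- fix_clean_wh()
  tl <- g$truth_log$injected_episodes
  expect_gt(nrow(tl), 0)
  for (iv in unique(wh$tables$intervention$intervention_id)) {
    ivr <- wh$tables$intervention[intervention_id == iv]
    per <- make_period(ivr$room_entry_ts, ivr$room_exit_ts)
    s <- wh$tables$measurement[intervention_id == iv & signal_code == "MAP"]
    eps <- detect_episodes(s, per, 65, "below", min_duration_s = 60,
                           max_gap_s = 300)
    truth <- tl[intervention_id == iv]
    expect_identical(nrow(eps), nrow(truth))
    if (nrow(eps)) {
      setorder(eps, start_ts); setorder(truth, start_ts)
      expect_equal(as.numeric(eps$start_ts), as.numeric(truth$start_ts))
      expect_equal(eps$duration_s,
                   as.numeric(truth$end_ts - truth$start_ts, units = "secs"))
    }
  }
})

test_that("perturbing non-ok samples never changes a feature value", {
  wh <- fix_clean_wh()
  intraop <- period_rule("intraop", "anesthesia start", 0, "anesthesia end", 0)
  spec <- list(
    feature_def("map_mean", intraop, "MAP", "mean"),
    feature_def("map_t65", intraop, "MAP", "total_time_s",
                threshold = 65, direction = "below"))
  # flag some samples non-ok, then distort their values wildly
  wh2 <- list(tables = lapply(wh$tables, data.table::copy))
  class(wh2) <- "warehouse"
  set.seed(7)
  idx <- sample(nrow(wh2$tables$measurement), 500)
  wh2$tables$measurement[idx, quality_flag := "out_of_range"]
  base <- extract_features(wh2, spec)
  wh2$tables$measurement[idx, value := value - 1000]
  expect_identical(extract_features(wh2, spec), base)
})

test_that("extraction yields one row per (intervention, feature) with reasons", {
  wh <- fix_clean_wh()
  n_iv <- nrow(wh$tables$intervention)
  intraop <- period_rule("intraop", "anesthesia start", 0, "anesthesia end", 0)
  f1 <- list(feature_def("map_mean", intraop, "MAP", "mean"))
  t1 <- extract_features(wh, f1)
  expect_identical(nrow(t1), n_iv)
  f2 <- c(f1, list(feature_def("hr_max", intraop, "HR", "max")))
  t2 <- extract_features(wh, f2)
  expect_identical(nrow(t2), 2L * n_iv)
  expect_identical(extract_features(wh, f2), t2)  # deterministic
  expect_error(extract_features(wh, list(feature_def("x", intraop, "MAP",
                                                     "entropy"))),
               class = "config_error")
  expect_error(extract_features(wh, list(feature_def("x", intraop, "XYZ",
                                                     "mean"))),
               class = "config_error")
  # missing anchors produce null rows with a reason, not failures
  wh3 <- list(tables = lapply(wh$tables, data.table::copy))
  class(wh3) <- "warehouse"
  iv1 <- wh3$tables$intervention$intervention_id[1]
  wh3$tables$event_record <- wh3$tables$event_record[
    !(intervention_id == iv1 & event_label == "anesthesia start")]
  t3 <- extract_features(wh3, f1)
  bad <- t3[intervention_id == iv1]
  expect_true(is.na(bad$value))
  expect_identical(bad$reason, "period_undefined")
})
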