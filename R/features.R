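# Per-intervention, per-period intraoperative features: summary statistics
# and threshold-episode features (episode count, time beyond threshold, area
# between signal and threshold). The signal between samples is modeled as a
# last-observation-carried-forward (LOCF) step function: the sample at t_i
# holds until min(t_{i+1}, t_i + max_gap_s, period end). This makes episode
# time and area exact rectangle sums, monotone in the threshold, and
# trivially checkable by per-second brute force.

#' Define a period of interest from anchor events
#'
#' A period rule names a start and an end anchor event plus second offsets;
#' [define_period()] instantiates it against one intervention's events,
#' yielding the half-open interval
#' `[start_event.ts + start_offset, end_event.ts + end_offset)`.
#'
#' @param name period name (e.g. `"intraop"`).
#' @param start_event,end_event canonical event labels; each must occur
#'   exactly once for the intervention.
#' @param start_offset_s,end_offset_s offsets in seconds.
#' @return `period_rule()`: a `period_rule`; `define_period()`: a `period`
#'   (list with `name`, `start_ts`, `end_ts`).
#' @export
#' @examples
#' period_rule("surgery", "surgery start", end_event = "surgery end")
period_rule <- function(name, start_event, start_offset_s = 0,
                        end_event, end_offset_s = 0) {
  structure(list(name = name, start_event = start_event,
                 start_offset_s = start_offset_s, end_event = end_event,
                 end_offset_s = end_offset_s), class = "period_rule")
}

#' @rdname period_rule
#' @param events data.table (`event_label`, `ts`) for a single intervention.
#' @param rule a `period_rule`.
#' @export
define_period <- function(events, rule) {
  ev <- as.data.table(events)
  anchor <- function(label) {
    ts <- ev[event_label == label, ts]
    if (length(ts) == 0)
      stop_pdw("anchor event '%s' not found", "period_undefined", label)
    if (length(ts) > 1)
      stop_pdw("anchor event '%s' occurs %d times (at %s)", "period_undefined",
               label, length(ts), paste(fmt_ts(ts), collapse = ", "))
    ts
  }
  start_ts <- anchor(rule$start_event) + rule$start_offset_s
  end_ts <- anchor(rule$end_event) + rule$end_offset_s
  if (!(start_ts < end_ts))
    stop_pdw("period '%s' is empty or inverted: [%s, %s)", "invalid_period",
             rule$name, fmt_ts(start_ts), fmt_ts(end_ts))
  structure(list(name = rule$name, start_ts = start_ts, end_ts = end_ts),
            class = "period")
}

# samples of one signal usable for features: ok-flagged, inside the period
usable_samples <- function(series, period) {
  s <- as.data.table(series)
  if ("quality_flag" %in% names(s)) s <- s[quality_flag == "ok"]
  s <- s[ts >= period$start_ts & ts < period$end_ts]
  setorder(s, ts)
  s
}

#' Summary statistics of a signal over a period
#'
#' Count, minimum, maximum, mean and median of the ok-flagged samples whose
#' timestamp falls in the half-open period. With zero usable samples the
#' count is 0 and the other statistics are `NA` (not an error). The median of
#' an even number of samples is the midpoint of the two central order
#' statistics.
#'
#' @param series data.table (`ts`, `value`, optional `quality_flag`).
#' @param period a `period` from [define_period()].
#' @return named list: `count`, `min`, `max`, `mean`, `median`.
#' @export
summarize_period <- function(series, period) {
  s <- usable_samples(series, period)
  if (nrow(s) == 0)
    return(list(count = 0L, min = NA_real_, max = NA_real_,
                mean = NA_real_, median = NA_real_))
  list(count = nrow(s), min = min(s$value), max = max(s$value),
       mean = mean(s$value), median = median(s$value))
}

#' Detect threshold episodes in a sampled vital-sign series
#'
#' Under the LOCF step model, maximal stretches of held time where the value
#' is strictly beyond the threshold (`value < threshold` for `"below"`,
#' `value > threshold` for `"above"`) form candidate episodes; candidates
#' shorter than `min_duration_s` are discarded. A sample's influence ends at
#' the next sample, after `max_gap_s` of silence, or at the period end,
#' whichever comes first — so monitoring dropouts longer than `max_gap_s`
#' split episodes rather than bridging them. Episode area is the rectangle
#' sum of `|value - threshold| * held duration` over the episode's samples
#' (signal unit x seconds), the "burden" of e.g. intraoperative hypotension.
#'
#' @inheritParams summarize_period
#' @param threshold numeric threshold in the signal's unit.
#' @param direction `"below"` or `"above"`.
#' @param min_duration_s minimum episode duration in seconds (default 60,
#'   i.e. two 30 s samples).
#' @param max_gap_s maximum seconds a sample is carried forward (default
#'   300).
#' @return data.table, one row per episode: `start_ts`, `end_ts`,
#'   `duration_s`, `area`, `deepest_value`, `n_samples`, `threshold`,
#'   `direction`.
#' @export
#' @examples
#' per <- structure(list(name = "w",
#'   start_ts = as.POSIXct("2024-01-01 09:00:00", tz = "UTC"),
#'   end_ts = as.POSIXct("2024-01-01 09:02:30", tz = "UTC")), class = "period")
#' s <- data.frame(ts = per$start_ts + 30 * (0:4),
#'                 value = c(70, 60, 55, 60, 70))
#' detect_episodes(s, per, threshold = 65, direction = "below",
#'                 min_duration_s = 0, max_gap_s = 60)
detect_episodes <- function(series, period, threshold,
                            direction = c("below", "above"),
                            min_duration_s = 60, max_gap_s = 300) {
  direction <- match.arg(direction)
  assert_that(min_duration_s >= 0, "min_duration_s must be non-negative")
  assert_that(max_gap_s > 0, "max_gap_s must be positive")
  empty <- data.table(start_ts = as_utc(character()),
                      end_ts = as_utc(character()), duration_s = numeric(),
                      area = numeric(), deepest_value = numeric(),
                      n_samples = integer(), threshold = numeric(),
                      direction = character())
  s <- usable_samples(series, period)
  if (nrow(s) == 0) return(empty)

  t <- as.numeric(s$ts)
  v <- s$value
  p_end <- as.numeric(period$end_ts)
  held_end <- pmin(c(t[-1], Inf), t + max_gap_s, p_end)
  beyond <- if (direction == "below") v < threshold else v > threshold

  # a new episode starts at each beyond-sample not seamlessly covered by the
  # previous beyond-sample's hold
  n <- length(t)
  prev_covers <- c(FALSE, beyond[-n] & (t[-1] <= t[-n] + max_gap_s))
  new_ep <- beyond & !prev_covers
  ep_id <- cumsum(new_ep)
  ep_id[!beyond] <- NA_integer_
  if (all(is.na(ep_id))) return(empty)

  idx <- which(!is.na(ep_id))
  dt <- data.table(ep = ep_id[idx], t = t[idx], v = v[idx],
                   held = held_end[idx] - t[idx],
                   dev = abs(v[idx] - threshold))
  ep <- dt[, .(
    start_ts = as_utc(as.POSIXct(min(t), origin = "1970-01-01", tz = "UTC")),
    end_ts = as_utc(as.POSIXct(max(t + held), origin = "1970-01-01", tz = "UTC")),
    duration_s = max(t + held) - min(t),
    area = sum(dev * held),
    deepest_value = if (direction == "below") min(v) else max(v),
    n_samples = .N
  ), by = ep][, ep := NULL]
  ep <- ep[duration_s >= min_duration_s]
  ep[, `:=`(threshold = threshold, direction = direction)]
  ep[]
}

#' Aggregate episode-level features
#'
#' Sums episode count, total time and total burden over the episodes of one
#' (series, period, threshold), and reports the deepest value reached (the
#' minimum sample for `"below"` episodes, the maximum for `"above"`). With
#' no episodes everything is zero and the deepest value is `NA`.
#'
#' @param episodes data.table from [detect_episodes()].
#' @param period the `period` the episodes were detected in (used for
#'   context only).
#' @return named list: `n_episodes`, `total_time_s`, `total_area`,
#'   `deepest_value`.
#' @export
episode_features <- function(episodes, period = NULL) {
  ep <- as.data.table(episodes)
  if (nrow(ep) == 0)
    return(list(n_episodes = 0L, total_time_s = 0, total_area = 0,
                deepest_value = NA_real_))
  assert_that(uniqueN(ep$threshold) == 1 && uniqueN(ep$direction) == 1,
              "episodes mix thresholds or directions")
  list(
    n_episodes = nrow(ep),
    total_time_s = sum(ep$duration_s),
    total_area = sum(ep$area),
    deepest_value = if (ep$direction[1] == "below") min(ep$deepest_value)
                    else max(ep$deepest_value)
  )
}

#' Declare features for extraction
#'
#' Each feature yields exactly one value per intervention: a summary
#' statistic (`count`, `min`, `max`, `mean`, `median`) or an episode
#' aggregate (`n_episodes`, `total_time_s`, `total_area`, `deepest_value`,
#' which require `threshold` and `direction`).
#'
#' @param name feature name (column name after pivoting).
#' @param period a [period_rule()].
#' @param signal a signal code present in the warehouse signal dimension.
#' @param kind one of the kinds above.
#' @param threshold,direction episode parameters (episode kinds only).
#' @param min_duration_s,max_gap_s episode detection parameters.
#' @return a `feature_def`.
#' @export
feature_def <- function(name, period, signal, kind,
                        threshold = NULL, direction = NULL,
                        min_duration_s = 60, max_gap_s = 300) {
  kinds <- c("count", "min", "max", "mean", "median",
             "n_episodes", "total_time_s", "total_area", "deepest_value")
  assert_that(kind %in% kinds, "unknown feature kind '%s'",
              class = "config_error", k = kind)
  episodic <- kind %in% c("n_episodes", "total_time_s", "total_area",
                          "deepest_value")
  if (episodic)
    assert_that(!is.null(threshold) && !is.null(direction),
                "episode features need threshold and direction",
                class = "config_error")
  structure(list(name = name, period = period, signal = signal, kind = kind,
                 threshold = threshold, direction = direction,
                 min_duration_s = min_duration_s, max_gap_s = max_gap_s,
                 episodic = episodic),
            class = "feature_def")
}

#' Extract a long-form feature table from the warehouse
#'
#' Computes every declared feature for every intervention in the warehouse,
#' using only ok-flagged measurements. Interventions for which a period
#' cannot be defined (missing or duplicated anchor events) receive a null
#' value with a reason code instead of failing the run.
#'
#' @param wh a `warehouse`.
#' @param feature_spec a list of [feature_def()]s.
#' @return data.table: `intervention_id`, `period`, `feature`, `value`,
#'   `unit`, `n_samples_used`, `reason`.
#' @export
extract_features <- function(wh, feature_spec) {
  if (inherits(feature_spec, "feature_def")) feature_spec <- list(feature_spec)
  assert_that(all(vapply(feature_spec, inherits, TRUE, "feature_def")),
              "feature_spec must be a list of feature_def objects",
              class = "config_error")
  known_signals <- wh$tables$signal$signal_code
  for (fd in feature_spec)
    assert_that(fd$signal %in% known_signals,
                "unknown signal '%s' in feature '%s'", class = "config_error",
                s = fd$signal, f = fd$name)

  sigunit <- setNames(wh$tables$signal$unit, wh$tables$signal$signal_code)
  ivs <- wh$tables$intervention$intervention_id
  ev_all <- wh$tables$event_record
  ms_all <- wh$tables$measurement

  rows <- vector("list", length(ivs) * length(feature_spec))
  k <- 0L
  for (iv in ivs) {
    ev <- ev_all[intervention_id == iv]
    ms <- ms_all[intervention_id == iv]
    period_cache <- list()
    for (fd in feature_spec) {
      k <- k + 1L
      pname <- fd$period$name
      per <- period_cache[[pname]]
      if (is.null(per)) {
        per <- tryCatch(define_period(ev, fd$period), periopdw_error = identity)
        period_cache[[pname]] <- per
      }
      if (inherits(per, "condition")) {
        rows[[k]] <- data.table(intervention_id = iv, period = pname,
                                feature = fd$name, value = NA_real_,
                                unit = NA_character_, n_samples_used = 0L,
                                reason = class(per)[1])
        next
      }
      series <- ms[signal_code == fd$signal]
      if (fd$episodic) {
        eps <- detect_episodes(series, per, fd$threshold, fd$direction,
                               fd$min_duration_s, fd$max_gap_s)
        agg <- episode_features(eps)
        val <- agg[[fd$kind]]
        unit <- switch(fd$kind,
                       n_episodes = "",
                       total_time_s = "s",
                       total_area = paste0(sigunit[fd$signal], "*s"),
                       deepest_value = sigunit[fd$signal])
        n_used <- nrow(usable_samples(series, per))
      } else {
        sm <- summarize_period(series, per)
        val <- sm[[fd$kind]]
        unit <- if (fd$kind == "count") "" else sigunit[fd$signal]
        n_used <- sm$count
      }
      rows[[k]] <- data.table(intervention_id = iv, period = pname,
                              feature = fd$name, value = as.numeric(val),
                              unit = unit, n_samples_used = as.integer(n_used),
                              reason = "ok")
    }
  }
  out <- rbindlist(rows)
  setorder(out, intervention_id, period, feature)
  out[]
}
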