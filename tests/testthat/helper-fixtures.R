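library(data.table)

# ---- shared fixtures, built once per test run ----------------------------

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# a small clean bundle with injected MAP<65 episodes
fix_clean_gen <- function() {
  fixture("clean_gen", function() {
    generate_bundle(6, interventions_per_patient = 1.2, seed = 401,
                    episode_spec = episode_spec("MAP", 65, "below",
                                                episode_rate = 2))
  })
}

# load a full bundle into a warehouse: one flow-1 run plus weekly flow-2 runs
load_full <- function(gen, config = etl_config()) {
  stg <- transform_staging(gen, config)
  wh <- wh_init(config)
  or_dates <- as.Date(gen$bundle$interventions$room_entry_ts, tz = "UTC")
  wh <- load_flow1(wh, stg, max(gen$bundle$stays$discharge_date) + 1)
  for (d in as.list(seq(min(or_dates) + 13, max(or_dates) + 14, by = 7)))
    wh <- load_flow2(wh, stg, d)
  wh
}

fix_clean_wh <- function() {
  fixture("clean_wh", function() load_full(fix_clean_gen()))
}

# ---- helpers -------------------------------------------------------------

make_period <- function(start_ts, end_ts, name = "w") {
  structure(list(name = name,
                 start_ts = as.POSIXct(start_ts, tz = "UTC"),
                 end_ts = as.POSIXct(end_ts, tz = "UTC")),
            class = "period")
}

# a 30 s grid series starting at a fixed origin
grid_series <- function(values, t0 = "2024-03-01 09:00:00", step = 30) {
  data.table(ts = as.POSIXct(t0, tz = "UTC") + step * (seq_along(values) - 1),
             value = values)
}

# ---- independent episode oracle ------------------------------------------
# Evaluates the LOCF step function second by second: for each second s in the
# period, the value is that of the last sample at t <= s with s < t + max_gap.
# Episodes are maximal runs of beyond-threshold seconds; area accumulates
# |value - threshold| per second. Deliberately naive - nothing shared with
# detect_episodes().
brute_force_episodes <- function(series, period, threshold, direction,
                                 min_duration_s = 60, max_gap_s = 300) {
  s <- as.data.table(series)
  if ("quality_flag" %in% names(s)) s <- s[quality_flag == "ok"]
  s <- s[ts >= period$start_ts & ts < period$end_ts]
  setorder(s, ts)
  t0 <- as.numeric(period$start_ts)
  t1 <- as.numeric(period$end_ts)
  secs <- seq(t0, t1 - 1)
  empty <- data.table(start_s = numeric(), duration_s = numeric(),
                      area = numeric())
  if (nrow(s) == 0) return(empty)
  st <- as.numeric(s$ts)
  idx <- findInterval(secs, st)               # last sample at or before s
  covered <- idx >= 1 & (secs < st[pmax(idx, 1)] + max_gap_s)
  val <- rep(NA_real_, length(secs))
  val[covered] <- s$value[idx[covered]]
  beyond <- !is.na(val) &
    (if (direction == "below") val < threshold else val > threshold)
  if (!any(beyond)) return(empty)
  r <- rle(beyond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  out <- rbindlist(lapply(runs, function(k) {
    i <- starts[k]:ends[k]
    data.table(start_s = secs[i[1]], duration_s = length(i),
               area = sum(abs(val[i] - threshold)))
  }))
  out[duration_s >= min_duration_s]
}

# pooled Newton-Raphson logistic fit, written independently of the package
# (loop over rows, no matrix shortcuts shared with the implementation)
pooled_newton_path <- function(X, y, tol = 1e-8, max_iter = 25) {
  p <- ncol(X)
  beta <- rep(0, p)
  path <- list(beta)
  for (it in seq_len(max_iter)) {
    g <- rep(0, p)
    H <- matrix(0, p, p)
    for (i in seq_len(nrow(X))) {
      xi <- X[i, ]
      mu <- 1 / (1 + exp(-sum(xi * beta)))
      g <- g + xi * (y[i] - mu)
      H <- H + (mu * (1 - mu)) * tcrossprod(xi)
    }
    if (max(abs(g)) <= tol) break
    beta <- beta + solve(H, g)
    path[[length(path) + 1]] <- beta
  }
  list(beta = beta, path = path, vcov = solve(H))
}
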