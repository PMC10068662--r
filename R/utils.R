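# shared internal helpers: error signalling, timestamp formatting, rounding

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pdw <- function(msg, class, ...) {
  # unname so argument names never partially match sprintf's formals
  message <- do.call(sprintf, c(list(msg), unname(list(...))))
  stop(structure(
    class = c(class, "periopdw_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

assert_that <- function(cond, msg, class = "invalid_argument", ...) {
  if (!isTRUE(cond)) stop_pdw(msg, class, ...)
  invisible(TRUE)
}

#' @noRd
as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  as.POSIXct(x, tz = "UTC")
}

fmt_ts <- function(x) {
  out <- format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  out[is.na(x)] <- NA_character_
  out
}

parse_ts <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

fmt_date <- function(x) {
  out <- format(x, "%Y-%m-%d")
  out[is.na(x)] <- NA_character_
  out
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; clinical summary tables conventionally
#' round half up, so 62.05 prints as 62.1. A small epsilon absorbs binary
#' representation error (e.g. 62.0155... stored just below the printed value).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# deterministic child seeds below 2^31, for scripts that need several streams
child_seed <- function(seed, k) (as.integer(seed) * 113L + k * 7919L) %% 2147483647L

# sample() treats a length-1 numeric x as 1:x; this always samples elements
safe_sample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}
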