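#' Uniformly sampled time series
#'
#' The universal currency between pipeline stages: a numeric vector sampled at
#' a fixed rate, with the time (in seconds) of the first sample. Sample `i`
#' sits at `t0 + (i - 1) / rate_hz`.
#'
#' @param values Numeric vector, length >= 2. `NA` is allowed only where a
#'   stage explicitly documents missing values (e.g. fully masked spectral
#'   columns); constructors of raw signals reject non-finite input.
#' @param rate_hz Sampling rate in samples per second (> 0).
#' @param t0 Time of the first sample, seconds.
#' @param allow_na Permit `NA` values (used by band summaries under COI
#'   masking).
#' @return An object of class `duet_ts`.
#' @export
time_series <- function(values, rate_hz, t0 = 0, allow_na = FALSE) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("time_series needs at least 2 samples")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || !is.finite(rate_hz) ||
      rate_hz <= 0) {
    stop("rate_hz must be a single positive number")
  }
  if (!allow_na && any(!is.finite(values))) {
    stop("time_series values must be finite")
  }
  structure(list(values = values, rate_hz = rate_hz, t0 = t0),
            class = "duet_ts")
}

#' Sample times of a time series
#' @param x A `duet_ts`.
#' @return Numeric vector of times in seconds.
#' @export
ts_times <- function(x) {
  stopifnot(inherits(x, "duet_ts"))
  x$t0 + (seq_along(x$values) - 1) / x$rate_hz
}

#' @export
length.duet_ts <- function(x) length(x$values)

#' @export
print.duet_ts <- function(x, ...) {
  cat(sprintf("<duet_ts> %d samples @ %g Hz, t0 = %g s (%.2f s)\n",
              length(x$values), x$rate_hz, x$t0,
              length(x$values) / x$rate_hz))
  invisible(x)
}

#' Duration of a time series in seconds
#' @param x A `duet_ts`.
#' @export
ts_duration <- function(x) length(x$values) / x$rate_hz

#' Resample a time series onto a new uniform grid
#'
#' Linear interpolation onto the target grid; values outside the source
#' support are held at the edge values. Used to bring audio-rate features
#' (100 Hz) onto the movement frame grid (25 Hz).
#'
#' @param x A `duet_ts`.
#' @param rate_hz Target rate.
#' @param n Target length (default: spans the source duration).
#' @param t0 Target start time (default: source `t0`).
#' @return A `duet_ts` at the target rate.
#' @export
ts_resample <- function(x, rate_hz, n = NULL, t0 = NULL) {
  stopifnot(inherits(x, "duet_ts"))
  if (is.null(t0)) t0 <- x$t0
  if (is.null(n)) n <- max(2L, floor(ts_duration(x) * rate_hz))
  tt <- t0 + (seq_len(n) - 1) / rate_hz
  out <- stats::approx(ts_times(x), x$values, xout = tt, rule = 2)$y
  time_series(out, rate_hz, t0)
}
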