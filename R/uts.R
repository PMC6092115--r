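#' Uniformly sampled time series
#'
#' The basic single-channel container used by every analysis stage: a
#' numeric vector sampled at a fixed rate `fs`, starting at time `t0`.
#' Sample `i` (1-based) is taken at `t0 + (i - 1) / fs` seconds.
#'
#' @param values numeric vector of samples; at least 2, all finite.
#' @param fs sampling rate in Hz; must be a single positive number.
#' @param t0 time of the first sample in seconds (default 0).
#' @param label channel name, e.g. `"acc_vertical"` or `"ml_force"`.
#' @param units physical units of the samples, e.g. `"m/s^2"`, `"N"`, `"cm"`.
#'
#' @return An object of class `uniform_ts`: a list with fields `label`,
#'   `fs`, `t0`, `values`, `units`.
#' @examples
#' x <- uniform_ts(sin(2 * pi * 2 * (0:999) / 200), fs = 200,
#'                 label = "acc_vertical", units = "m/s^2")
#' range(ts_time(x))
#' @export
uniform_ts <- function(values, fs, t0 = 0, label = "", units = "") {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a uniform time series needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(values)))
    stop("all samples must be finite (no NA/NaN/Inf)", call. = FALSE)
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    stop("`t0` must be a single finite number (s)", call. = FALSE)
  structure(list(label = as.character(label), fs = fs, t0 = as.numeric(t0),
                 values = values, units = as.character(units)),
            class = "uniform_ts")
}

#' Sample timestamps of a uniform time series
#'
#' @param x a [uniform_ts()] object.
#' @return Numeric vector of sample times in seconds.
#' @export
ts_time <- function(x) {
  stopifnot(inherits(x, "uniform_ts"))
  x$t0 + (seq_along(x$values) - 1) / x$fs
}

#' Duration of a uniform time series
#'
#' Time between first and last sample, `(n - 1) / fs` seconds.
#'
#' @param x a [uniform_ts()] object.
#' @return Duration in seconds.
#' @export
ts_duration <- function(x) {
  stopifnot(inherits(x, "uniform_ts"))
  (length(x$values) - 1) / x$fs
}

# indices of samples with t in the half-open interval [from, to); a small
# absolute tolerance absorbs floating-point jitter in the time grid
idx_in_interval <- function(t, from, to, eps = 1e-9) {
  which(t >= from - eps & t < to - eps)
}

#' @export
print.uniform_ts <- function(x, ...) {
  cat(sprintf("<uniform_ts> %s [%s]: %d samples @ %g Hz, t = [%.4g, %.4g] s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              if (nzchar(x$units)) x$units else "?",
              length(x$values), x$fs, x$t0, x$t0 + ts_duration(x)))
  invisible(x)
}
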