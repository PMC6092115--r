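#' Baseline mean and standard deviation of a quiet interval
#'
#' Summary statistics of the samples whose timestamps fall in the
#' half-open interval `[t_start, t_end)`. Used as the reference for
#' threshold-based onset detection ("two standard deviations above the
#' mean of the baseline").
#'
#' @param series a [uniform_ts()] object.
#' @param interval numeric length-2, `c(t_start, t_end)` in seconds;
#'   must contain at least 2 samples.
#' @return An object of class `baseline_stats`: list with `interval`,
#'   `mean`, `sd` (sample SD, n - 1 denominator) and `n`.
#' @export
baseline_stats <- function(series, interval) {
  stopifnot(inherits(series, "uniform_ts"))
  if (!is.numeric(interval) || length(interval) != 2L || interval[2] <= interval[1])
    stop("`interval` must be c(t_start, t_end) with t_end > t_start", call. = FALSE)
  t <- ts_time(series)
  idx <- idx_in_interval(t, interval[1], interval[2])
  if (length(idx) < 2L)
    stop("baseline interval contains fewer than 2 samples", call. = FALSE)
  x <- series$values[idx]
  structure(list(interval = as.numeric(interval), mean = mean(x),
                 sd = stats::sd(x), n = length(idx)),
            class = "baseline_stats")
}

#' Threshold-crossing onset detection against a quiet baseline
#'
#' Returns the time of the first sample at or after `search_from` whose
#' deviation from the baseline mean exceeds `k` baseline standard
#' deviations and stays beyond the threshold for at least `min_hold`
#' seconds. The hold requirement rejects isolated noise spikes. Absence
#' of a qualifying crossing is a valid outcome, reported as `NA` (not an
#' error).
#'
#' `polarity` selects the deviation convention: `"above"` (signal rises
#' above the mean), `"below"` (falls below), or `"absolute"` (either
#' direction; the default, side-agnostic choice for mediolateral force).
#'
#' `sd_floor` is an absolute lower bound on the baseline SD so that
#' noise-free signals (baseline SD exactly 0) still yield a usable
#' threshold.
#'
#' @param series a [uniform_ts()] object.
#' @param baseline a [baseline_stats()] object.
#' @param k threshold multiplier on the baseline SD (default 2).
#' @param search_from time (s) at which the search starts; default the
#'   end of the baseline interval.
#' @param min_hold minimum time (s) the signal must stay beyond the
#'   threshold (default 0.05 s).
#' @param polarity `"absolute"`, `"above"` or `"below"`.
#' @param sd_floor absolute floor on the baseline SD, in signal units
#'   (default 1e-9).
#' @return Onset time in seconds, or `NA_real_` if no crossing qualifies.
#' @export
onset_by_threshold <- function(series, baseline, k = 2,
                               search_from = NULL, min_hold = 0.05,
                               polarity = c("absolute", "above", "below"),
                               sd_floor = 1e-9) {
  stopifnot(inherits(series, "uniform_ts"), inherits(baseline, "baseline_stats"))
  polarity <- match.arg(polarity)
  if (min_hold < 0) stop("`min_hold` must be >= 0", call. = FALSE)
  t <- ts_time(series)
  if (is.null(search_from)) search_from <- baseline$interval[2]
  i0 <- which(t >= search_from - 1e-9)
  if (!length(i0))
    stop("`search_from` lies beyond the end of the series", call. = FALSE)
  i0 <- i0[1]
  dev <- switch(polarity,
                above = series$values - baseline$mean,
                below = baseline$mean - series$values,
                absolute = abs(series$values - baseline$mean))
  thr <- k * max(baseline$sd, sd_floor)
  ok <- dev[i0:length(dev)] > thr
  n_hold <- round(min_hold * series$fs)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # a run of L samples spans (L - 1)/fs seconds; it must complete within
  # the series, so truncated runs at the end only count by actual length
  cand <- which(r$values & r$lengths >= n_hold + 1L)
  if (!length(cand)) return(NA_real_)
  t[i0 + starts[cand[1]] - 1L]
}

#' Root-mean-square displacement about a reference
#'
#' `sqrt(mean((x - reference)^2))` over the samples in the half-open
#' interval `[t_start, t_end)`.
#'
#' @param series a [uniform_ts()] object.
#' @param interval numeric length-2, `c(t_start, t_end)` in seconds.
#' @param reference reference value in signal units (default 0).
#' @return Non-negative scalar in signal units.
#' @export
rms_displacement <- function(series, interval, reference = 0) {
  stopifnot(inherits(series, "uniform_ts"))
  if (!is.numeric(interval) || length(interval) != 2L || interval[2] <= interval[1])
    stop("`interval` must be c(t_start, t_end) with t_end > t_start", call. = FALSE)
  t <- ts_time(series)
  idx <- idx_in_interval(t, interval[1], interval[2])
  if (!length(idx))
    stop("interval contains no samples", call. = FALSE)
  sqrt(mean((series$values[idx] - reference)^2))
}
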