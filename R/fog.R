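#' Spectral band specification for the freeze index
#'
#' The freeze index compares peak spectral power in the freeze-trembling
#' band (default 3--8 Hz) with peak power in the locomotor band (default
#' 0.5--3 Hz); windows whose index exceeds `threshold` (default 2, the
#' clinical convention) are classified as freezing. The locomotor band
#' lower edge is configurable (some conventions use 0 Hz); the default
#' 0.5 Hz excludes the DC region.
#'
#' @param loco_band numeric length-2, locomotor band in Hz.
#' @param freeze_band numeric length-2, freeze band in Hz; must not
#'   overlap the locomotor band except at the shared edge.
#' @param threshold freeze classification threshold on the index.
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(loco_band = c(0.5, 3), freeze_band = c(3, 8), threshold = 2) {
  if (length(loco_band) != 2L || loco_band[1] >= loco_band[2] || loco_band[1] < 0)
    stop("`loco_band` must be c(lo, hi) with 0 <= lo < hi", call. = FALSE)
  if (length(freeze_band) != 2L || freeze_band[1] >= freeze_band[2])
    stop("`freeze_band` must be c(lo, hi) with lo < hi", call. = FALSE)
  if (freeze_band[1] < loco_band[2] - 1e-9)
    stop("bands may only touch at a shared edge, not overlap", call. = FALSE)
  if (!is.numeric(threshold) || threshold <= 0)
    stop("`threshold` must be positive", call. = FALSE)
  structure(list(loco_band = as.numeric(loco_band),
                 freeze_band = as.numeric(freeze_band),
                 threshold = as.numeric(threshold)),
            class = "band_spec")
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' One-sided power spectral density of an analysis window
#'
#' Extracts the window of length `span` centered at `t_center`, removes
#' its mean, applies a Hann taper (leakage control for peak-power
#' ratios), and returns the one-sided periodogram-based PSD. Frequency
#' resolution is `1/span`.
#'
#' @param series a [uniform_ts()] object.
#' @param t_center window center time in seconds.
#' @param span window length in seconds (default 7.5).
#' @return Object of class `fog_psd`: list with `freq` (Hz), `power`
#'   (signal units squared per Hz), `span` (realized, s), `fs`, `n`.
#' @export
window_psd <- function(series, t_center, span = 7.5) {
  stopifnot(inherits(series, "uniform_ts"))
  if (span <= 0) stop("`span` must be positive", call. = FALSE)
  n <- round(span * series$fs)
  if (n < 4L) stop("window too short for spectral analysis", call. = FALSE)
  i1 <- round((t_center - span / 2 - series$t0) * series$fs) + 1L
  i2 <- i1 + n - 1L
  if (i1 < 1L || i2 > length(series$values))
    stop("analysis window extends past the series", call. = FALSE)
  x <- series$values[i1:i2]
  x <- x - mean(x)
  w <- hann_window(n)
  X <- stats::fft(x * w)
  nf <- floor(n / 2) + 1L
  p <- (Mod(X[seq_len(nf)])^2) * 2 / (series$fs * sum(w^2))
  p[1] <- p[1] / 2
  if (n %% 2L == 0L) p[nf] <- p[nf] / 2
  structure(list(freq = (seq_len(nf) - 1L) * series$fs / n, power = p,
                 span = n / series$fs, fs = series$fs, n = n),
            class = "fog_psd")
}

#' Freeze index of one spectral window
#'
#' Peak power in the freeze band divided by peak power in the locomotor
#' band (band edges inclusive). When the locomotor peak falls below
#' `power_floor` the window carries no locomotion and the index is
#' undefined; `NA` is returned and such windows are excluded from event
#' calling.
#'
#' @param psd a [window_psd()] result.
#' @param bands a [band_spec()].
#' @param power_floor minimum locomotor peak power for the index to be
#'   defined (default 0, i.e. always defined unless the peak is 0).
#' @return The index (non-negative scalar), or `NA_real_` when invalid.
#' @export
fog_index <- function(psd, bands = band_spec(), power_floor = 0) {
  stopifnot(inherits(psd, "fog_psd"), inherits(bands, "band_spec"))
  inband <- function(b) psd$freq >= b[1] - 1e-9 & psd$freq <= b[2] + 1e-9
  li <- inband(bands$loco_band)
  fi <- inband(bands$freeze_band)
  if (!any(li) || !any(fi))
    stop("the PSD does not cover both analysis bands", call. = FALSE)
  loco <- max(psd$power[li])
  freeze <- max(psd$power[fi])
  if (loco < power_floor || loco <= 0) return(NA_real_)
  freeze / loco
}

# maximal runs of above-threshold windows -> coarse events, with runs
# separated by less than merge_gap merged
call_fog_events <- function(centers, above, hop, merge_gap) {
  ev <- data.frame(t_start = numeric(0), t_end = numeric(0))
  if (!any(above)) return(ev)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  ev <- data.frame(t_start = centers[starts[keep]] - hop / 2,
                   t_end = centers[ends[keep]] + hop / 2)
  if (nrow(ev) > 1L) {
    out <- ev[1, ]
    for (j in 2:nrow(ev)) {
      if (ev$t_start[j] - out$t_end[nrow(out)] < merge_gap) {
        out$t_end[nrow(out)] <- ev$t_end[j]
      } else {
        out <- rbind(out, ev[j, ])
      }
    }
    ev <- out
  }
  rownames(ev) <- NULL
  ev
}

# Refine coarse event edges with the freeze-band RMS envelope. The
# 7.5 s spectral windows smear event edges by up to half a window; the
# envelope of the 3-8 Hz band-passed signal rises at the true episode
# edge, and the crossing of the half-power level between the quiet and
# plateau envelope is an (asymptotically) unbiased edge estimate for a
# moving-RMS envelope, because squared RMS grows linearly with episode
# overlap.
refine_fog_edges <- function(series, events, bands, span, env_window = 0.5) {
  nyq <- series$fs / 2
  band <- pmin(bands$freeze_band, nyq * 0.99)
  ba <- signal::butter(2, band / nyq, type = "pass")
  fb <- dual_pass_ba(ba$b, ba$a, series$values,
                     default_padlen(length(ba$a) - 1L))
  env <- moving_rms(fb, series$fs, env_window)
  t <- ts_time(series)
  near <- rep(FALSE, length(t))
  for (j in seq_len(nrow(events)))
    near <- near | (t >= events$t_start[j] - span / 2 &
                    t <= events$t_end[j] + span / 2)
  base <- if (any(!near)) stats::median(env[!near]) else min(env)
  out <- events
  for (j in seq_len(nrow(events))) {
    mid <- (events$t_start[j] + events$t_end[j]) / 2
    half <- min(1, (events$t_end[j] - events$t_start[j]) / 2)
    core <- t >= mid - half & t <= mid + half
    if (!any(core)) next
    plateau <- stats::median(env[core])
    if (!(plateau > base)) next
    thr <- sqrt((plateau^2 + base^2) / 2)
    im <- which.min(abs(t - mid))
    if (env[im] < thr) next # envelope inconsistent with event; keep coarse
    lo <- im
    while (lo > 1L && env[lo - 1L] >= thr) lo <- lo - 1L
    hi <- im
    while (hi < length(env) && env[hi + 1L] >= thr) hi <- hi + 1L
    out$t_start[j] <- t[lo]
    out$t_end[j] <- t[hi]
  }
  # refinement cannot create overlaps out of disjoint coarse events, but
  # guard against degenerate orderings anyway
  out <- out[out$t_end > out$t_start, , drop = FALSE]
  if (nrow(out) > 1L) {
    keep <- c(TRUE, out$t_start[-1] > out$t_end[-nrow(out)])
    if (!all(keep)) {
      merged <- out[1, ]
      for (j in 2:nrow(out)) {
        if (out$t_start[j] <= merged$t_end[nrow(merged)]) {
          merged$t_end[nrow(merged)] <- max(merged$t_end[nrow(merged)], out$t_end[j])
        } else {
          merged <- rbind(merged, out[j, ])
        }
      }
      out <- merged
    }
  }
  rownames(out) <- NULL
  out
}

#' Detect freezing-of-gait episodes in a walking trial
#'
#' Computes the freeze index on sliding spectral windows (length `span`,
#' stride `hop`) over low-pass-filtered lumbar vertical acceleration.
#' Maximal runs of consecutive valid windows with index above the
#' threshold become candidate events (each window accounts for its
#' center +/- `hop/2`; runs closer than `merge_gap` are merged). Because
#' a 7.5 s window cannot localize episode edges, candidate edges are then
#' refined against the freeze-band amplitude envelope (disable with
#' `refine_edges = FALSE` to keep the raw window-run extent).
#'
#' @param series lumbar vertical acceleration, a [uniform_ts()].
#' @param bands a [band_spec()].
#' @param span spectral window length in seconds (default 7.5).
#' @param hop window stride in seconds (default 0.25).
#' @param merge_gap runs separated by less than this (s) merge (default 0.5).
#' @param threshold freeze threshold; defaults to `bands$threshold`.
#' @param prefilter a [filter_spec()] applied before analysis (default
#'   10 Hz dual-pass low-pass, matching the accelerometer conditioning),
#'   or `NULL` to skip.
#' @param refine_edges logical; refine event edges on the freeze-band
#'   envelope (default `TRUE`).
#' @param power_floor locomotor-peak validity floor; default
#'   `1e-12 * var(series)` flags windows with no locomotor content as
#'   invalid rather than returning an unbounded index.
#' @param marks optional `c(walk_start, walk_stop)` trial marks (s) used
#'   for gait time; when absent gait time is detected from the movement
#'   envelope (see [gait_time()]).
#' @return Object of class `fog_result`: list with `events` (data frame
#'   `t_start`, `t_end`), `total_fog_time` (s), `gait_time` (s), and
#'   `index` (data frame `t_center`, `fog_index`; `NA` = invalid window).
#' @export
detect_fog <- function(series, bands = band_spec(), span = 7.5, hop = 0.25,
                       merge_gap = 0.5, threshold = NULL,
                       prefilter = filter_spec(10, 2), refine_edges = TRUE,
                       power_floor = NULL, marks = NULL) {
  stopifnot(inherits(series, "uniform_ts"), inherits(bands, "band_spec"))
  dur <- ts_duration(series)
  if (dur < span)
    stop(sprintf("series (%.2f s) is shorter than the analysis window (%.2f s)",
                 dur, span), call. = FALSE)
  threshold <- threshold %||% bands$threshold
  x <- if (is.null(prefilter)) series else butter_dual_pass(series, prefilter)
  if (is.null(power_floor)) power_floor <- 1e-12 * stats::var(x$values)
  centers <- seq(x$t0 + span / 2, x$t0 + dur - span / 2 + 1e-9, by = hop)
  idx <- vapply(centers, function(tc)
    fog_index(window_psd(x, tc, span), bands, power_floor), numeric(1))
  above <- !is.na(idx) & idx > threshold
  events <- call_fog_events(centers, above, hop, merge_gap)
  if (refine_edges && nrow(events) > 0L)
    events <- refine_fog_edges(x, events, bands, span)
  events$t_start <- pmax(events$t_start, x$t0)
  events$t_end <- pmin(events$t_end, x$t0 + dur)
  gt <- gait_time(series, marks = marks)
  structure(list(events = events,
                 total_fog_time = sum(events$t_end - events$t_start),
                 gait_time = gt,
                 index = data.frame(t_center = centers, fog_index = idx)),
            class = "fog_result")
}

#' Gait time of a walking trial
#'
#' With explicit `marks = c(start, stop)` (from trial metadata) the gait
#' time is simply their difference. Without marks, movement is detected
#' from a 0.5 s moving-RMS envelope of the demeaned acceleration: gait
#' time is the span between the first and last envelope samples exceeding
#' the quiet-baseline envelope mean + `k` SD.
#'
#' @param series lumbar vertical acceleration, a [uniform_ts()].
#' @param marks optional `c(walk_start, walk_stop)` in seconds.
#' @param quiet_interval interval (s) assumed quiet for the baseline;
#'   default the first 0.5 s of the series.
#' @param env_window moving-RMS window (s), default 0.5.
#' @param k threshold multiplier (default 2).
#' @param sd_floor absolute floor on the baseline envelope SD.
#' @return Gait time in seconds.
#' @export
gait_time <- function(series, marks = NULL, quiet_interval = NULL,
                      env_window = 0.5, k = 2, sd_floor = 1e-9) {
  stopifnot(inherits(series, "uniform_ts"))
  if (!is.null(marks)) {
    if (length(marks) != 2L || marks[2] <= marks[1])
      stop("`marks` must be c(start, stop) with stop > start", call. = FALSE)
    return(marks[2] - marks[1])
  }
  t <- ts_time(series)
  if (is.null(quiet_interval)) quiet_interval <- c(t[1], t[1] + 0.5)
  env <- moving_rms(series$values - mean(series$values), series$fs, env_window)
  qi <- idx_in_interval(t, quiet_interval[1], quiet_interval[2])
  if (length(qi) < 2L)
    stop("quiet interval contains fewer than 2 samples", call. = FALSE)
  thr <- mean(env[qi]) + k * max(stats::sd(env[qi]), sd_floor)
  above <- which(env > thr)
  if (!length(above))
    stop("no movement detected and no start/stop marks provided", call. = FALSE)
  t[above[length(above)]] - t[above[1]]
}

#' @export
print.fog_result <- function(x, ...) {
  cat(sprintf("<fog_result> %d event(s), total FoG time %.2f s, gait time %.2f s\n",
              nrow(x$events), x$total_fog_time, x$gait_time))
  if (nrow(x$events)) print(x$events)
  invisible(x)
}
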