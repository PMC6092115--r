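#' Step-initiation trial container
#'
#' Bundles the two channels of a step-initiation trial: the mediolateral
#' ground-reaction force (the APA weight shift toward the supporting leg)
#' and the anteroposterior displacement of the stepping-foot malleolus
#' marker (the step itself), plus the quiet-standing baseline interval
#' and subject anthropometrics.
#'
#' @param ml_force mediolateral ground-reaction force (N), a [uniform_ts()].
#' @param ap_foot_disp anteroposterior stepping-foot marker displacement
#'   (cm), a [uniform_ts()] with the same `fs` and length as `ml_force`.
#' @param foot_length subject foot length in cm (> 0); normalizes APA
#'   amplitude to N/cm.
#' @param baseline_interval quiet-standing interval `c(start, end)` in
#'   seconds; default the first 1 s of the trial (the protocol starts in
#'   quiet stance).
#' @param stepping_side `"left"` or `"right"`.
#' @return An object of class `step_trial`.
#' @export
step_trial <- function(ml_force, ap_foot_disp, foot_length,
                       baseline_interval = NULL,
                       stepping_side = c("left", "right")) {
  stopifnot(inherits(ml_force, "uniform_ts"), inherits(ap_foot_disp, "uniform_ts"))
  stepping_side <- match.arg(stepping_side)
  if (ml_force$fs != ap_foot_disp$fs ||
      length(ml_force$values) != length(ap_foot_disp$values) ||
      abs(ml_force$t0 - ap_foot_disp$t0) > 1e-9)
    stop("force and displacement series must share fs, length and t0", call. = FALSE)
  if (!is.numeric(foot_length) || length(foot_length) != 1L || foot_length <= 0)
    stop("`foot_length` must be a positive length in cm", call. = FALSE)
  if (is.null(baseline_interval))
    baseline_interval <- c(ml_force$t0, ml_force$t0 + 1)
  if (length(baseline_interval) != 2L || baseline_interval[2] <= baseline_interval[1])
    stop("`baseline_interval` must be c(start, end) with end > start", call. = FALSE)
  structure(list(ml_force = ml_force, ap_foot_disp = ap_foot_disp,
                 baseline_interval = as.numeric(baseline_interval),
                 foot_length = foot_length, stepping_side = stepping_side),
            class = "step_trial")
}

#' APA onset in a step-initiation trial
#'
#' Time of the abrupt increase of the mediolateral force: the first
#' sustained excursion beyond `k` (default 2) baseline standard
#' deviations from the baseline mean, searched from the end of the
#' quiet-standing interval. The default polarity is the absolute
#' deviation from the baseline mean, which is agnostic to the plate-axis
#' sign convention; pass `polarity = "above"`/`"below"` for a signed
#' convention.
#'
#' @param trial a [step_trial()].
#' @param k threshold multiplier (default 2).
#' @param min_hold sustained-crossing requirement in seconds (default 0.05).
#' @param polarity deviation convention, see [onset_by_threshold()].
#' @return Onset time (s), or `NA_real_` when no crossing qualifies (the
#'   trial is then invalid and excluded from averages).
#' @export
detect_apa_onset <- function(trial, k = 2, min_hold = 0.05,
                             polarity = c("absolute", "above", "below")) {
  stopifnot(inherits(trial, "step_trial"))
  polarity <- match.arg(polarity)
  bl <- baseline_stats(trial$ml_force, trial$baseline_interval)
  onset_by_threshold(trial$ml_force, bl, k = k,
                     search_from = trial$baseline_interval[2],
                     min_hold = min_hold, polarity = polarity)
}

#' Step onset in a step-initiation trial
#'
#' Same 2-SD baseline rule as [detect_apa_onset()], applied to the
#' anteroposterior displacement of the stepping-foot marker. The search
#' starts at the APA onset when one is supplied (the step follows the
#' APA), which prevents baseline jitter from triggering.
#'
#' @param trial a [step_trial()].
#' @param apa_onset optional APA onset time (s); search starts there.
#' @inheritParams detect_apa_onset
#' @return Onset time (s), or `NA_real_` when no crossing qualifies.
#' @export
detect_step_onset <- function(trial, apa_onset = NULL, k = 2, min_hold = 0.05,
                              polarity = c("absolute", "above", "below")) {
  stopifnot(inherits(trial, "step_trial"))
  polarity <- match.arg(polarity)
  bl <- baseline_stats(trial$ap_foot_disp, trial$baseline_interval)
  from <- if (is.null(apa_onset) || is.na(apa_onset))
    trial$baseline_interval[2] else apa_onset
  onset_by_threshold(trial$ap_foot_disp, bl, k = k, search_from = from,
                     min_hold = min_hold, polarity = polarity)
}

#' APA metrics of one step-initiation trial
#'
#' APA duration is the time between APA onset (mediolateral force) and
#' step onset (anteroposterior foot displacement). APA peak amplitude is
#' the maximum absolute deviation of the mediolateral force from its
#' baseline mean between the two onsets, normalized by foot length
#' (N/cm).
#'
#' @param trial a [step_trial()].
#' @inheritParams detect_apa_onset
#' @return Object of class `apa_metrics`: list with `apa_onset`,
#'   `step_onset`, `apa_duration` (s), `apa_peak_amplitude` (N/cm),
#'   `valid` (logical) and `note` (why the trial is invalid, if it is).
#'   Invalid trials (no detectable onset, or step before APA) are flagged
#'   rather than silently clamped.
#' @examples
#' tr <- gen_step_trial(seed = 42)
#' apa_metrics(tr$trial)
#' @export
apa_metrics <- function(trial, k = 2, min_hold = 0.05,
                        polarity = c("absolute", "above", "below")) {
  stopifnot(inherits(trial, "step_trial"))
  polarity <- match.arg(polarity)
  out <- structure(list(apa_onset = NA_real_, step_onset = NA_real_,
                        apa_duration = NA_real_, apa_peak_amplitude = NA_real_,
                        valid = FALSE, note = ""),
                   class = "apa_metrics")
  apa <- detect_apa_onset(trial, k = k, min_hold = min_hold, polarity = polarity)
  if (is.na(apa)) {
    out$note <- "no APA onset detected in mediolateral force"
    return(out)
  }
  step <- detect_step_onset(trial, apa_onset = apa, k = k,
                            min_hold = min_hold, polarity = polarity)
  out$apa_onset <- apa
  if (is.na(step)) {
    out$note <- "no step onset detected in foot displacement"
    return(out)
  }
  out$step_onset <- step
  if (step < apa) {
    out$note <- "step onset precedes APA onset"
    return(out)
  }
  bl <- baseline_stats(trial$ml_force, trial$baseline_interval)
  t <- ts_time(trial$ml_force)
  idx <- which(t >= apa - 1e-9 & t <= step + 1e-9)
  out$apa_duration <- step - apa
  out$apa_peak_amplitude <-
    max(abs(trial$ml_force$values[idx] - bl$mean)) / trial$foot_length
  out$valid <- TRUE
  out
}

#' @export
print.apa_metrics <- function(x, ...) {
  if (!x$valid) {
    cat(sprintf("<apa_metrics> invalid trial: %s\n", x$note))
  } else {
    cat(sprintf(paste0("<apa_metrics> APA onset %.3f s, step onset %.3f s, ",
                       "duration %.3f s, peak amplitude %.3f N/cm\n"),
                x$apa_onset, x$step_onset, x$apa_duration, x$apa_peak_amplitude))
  }
  invisible(x)
}
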