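#' Trapezoidal-velocity platform displacement profile
#'
#' Generates the support-surface translation used in the perturbation
#' protocol: constant acceleration `peak_acceleration` up to
#' `peak_velocity`, a constant-velocity cruise, and a symmetric
#' deceleration, covering `amplitude` in total. The default protocol
#' parameters are amplitude 12 cm, peak velocity 15 cm/s and peak
#' acceleration 100 cm/s^2 (movement time 0.95 s). The triple must be
#' feasible: `peak_velocity^2 / peak_acceleration <= amplitude`; at
#' equality the profile is triangular (no cruise). A backward
#' translation is the convention, so displacement is negative
#' (`direction = -1`) with the AP axis positive forward.
#'
#' The displacement is evaluated in closed form at each sample time, so
#' sampled peak displacement, velocity (central difference) and
#' acceleration (second difference) reproduce the protocol parameters to
#' well within 1% at 200 Hz.
#'
#' @param amplitude total displacement in cm (default 12).
#' @param peak_velocity cruise velocity in cm/s (default 15).
#' @param peak_acceleration ramp acceleration in cm/s^2 (default 100).
#' @param fs sampling rate in Hz (default 200).
#' @param onset movement start time (s) within the output series.
#' @param total_duration length of the output series (s); default
#'   `onset + movement time`.
#' @param direction `-1` (backward, default) or `+1`.
#' @return `uniform_ts` of platform AP displacement (cm), with the
#'   movement time attached as `attr(., "movement_time")`.
#' @examples
#' p <- gen_platform_profile()
#' attr(p, "movement_time") # 0.95 s with the default parameters
#' @export
gen_platform_profile <- function(amplitude = 12, peak_velocity = 15,
                                 peak_acceleration = 100, fs = 200,
                                 onset = 0, total_duration = NULL,
                                 direction = -1) {
  if (amplitude <= 0 || peak_velocity <= 0 || peak_acceleration <= 0)
    stop("amplitude, peak_velocity and peak_acceleration must be positive",
         call. = FALSE)
  if (peak_velocity^2 / peak_acceleration > amplitude + 1e-9)
    stop(sprintf(paste0("infeasible profile: v^2/a = %.4g cm exceeds the ",
                        "amplitude %.4g cm"),
                 peak_velocity^2 / peak_acceleration, amplitude), call. = FALSE)
  a <- peak_acceleration
  v <- peak_velocity
  t_a <- v / a                      # acceleration phase
  d_a <- v^2 / (2 * a)              # distance covered per ramp
  d_c <- amplitude - 2 * d_a        # cruise distance (0 => triangular)
  t_c <- d_c / v
  t_move <- 2 * t_a + t_c
  if (is.null(total_duration)) total_duration <- onset + t_move
  if (total_duration < onset + t_move - 1e-9)
    stop("`total_duration` too short for the movement", call. = FALSE)
  t <- seq(0, total_duration, by = 1 / fs)
  tau <- t - onset
  x <- numeric(length(t))
  ph1 <- tau > 0 & tau <= t_a
  ph2 <- tau > t_a & tau <= t_a + t_c
  ph3 <- tau > t_a + t_c & tau <= t_move
  x[ph1] <- 0.5 * a * tau[ph1]^2
  x[ph2] <- d_a + v * (tau[ph2] - t_a)
  x[ph3] <- amplitude - 0.5 * a * (t_move - tau[ph3])^2
  x[tau > t_move] <- amplitude
  out <- uniform_ts(sign(direction) * x, fs = fs, t0 = 0,
                    label = "platform_ap", units = "cm")
  attr(out, "movement_time") <- t_move
  out
}

# derive a bounded per-trial seed from a base seed and a counter
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 997 + 104729 * as.numeric(i)) %% 2147483647)
}

#' Synthetic walking trial with injected freezing episodes
#'
#' Emulates lumbar vertical acceleration during walking: a locomotor
#' sinusoid (default 2 Hz) active over `walk_interval`, with each
#' freezing episode *replacing* the locomotor component by a
#' freeze-band sinusoid (halted progression with trembling), plus white
#' Gaussian sensor noise. Set `additive = TRUE` to superimpose the
#' trembling on continuing locomotion instead (robustness testing).
#'
#' @param duration trial length in seconds (default 60).
#' @param fs sampling rate (default 200 Hz).
#' @param loco_freq locomotor frequency in Hz (default 2).
#' @param loco_amp locomotor amplitude in m/s^2 (default 1).
#' @param freeze_episodes data frame with columns `t_start`, `t_end` and
#'   optionally `freeze_freq` (Hz, default 5, must lie in 3--8) and
#'   `amp` (default `3 * loco_amp`); episodes must fall inside
#'   `walk_interval` and must not overlap.
#' @param noise_sd white-noise SD in m/s^2 (default 0.1).
#' @param walk_interval `c(start, stop)` of locomotion (s); default
#'   `c(1, duration - 1)`.
#' @param additive superimpose trembling instead of replacing locomotion.
#' @param seed RNG seed; the generator is a pure function of its
#'   arguments and the seed.
#' @param out_prefix optional path prefix; when given, writes
#'   `<prefix>.csv`, `<prefix>.json` (sidecar) and `<prefix>_truth.json`.
#' @param meta optional named list merged into the sidecar metadata.
#' @return List with `series` (a [uniform_ts()]) and `truth` (episode
#'   table, total freeze time, walk interval, gait time, seed).
#' @export
gen_walk_trial <- function(duration = 60, fs = 200, loco_freq = 2,
                           loco_amp = 1, freeze_episodes = NULL,
                           noise_sd = 0.1, walk_interval = NULL,
                           additive = FALSE, seed = 1,
                           out_prefix = NULL, meta = list()) {
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  if (is.null(walk_interval)) walk_interval <- c(1, duration - 1)
  if (walk_interval[1] < 0 || walk_interval[2] > duration ||
      walk_interval[2] <= walk_interval[1])
    stop("`walk_interval` must lie inside the trial", call. = FALSE)
  ep <- freeze_episodes
  if (is.null(ep)) {
    ep <- data.frame(t_start = numeric(0), t_end = numeric(0),
                     freeze_freq = numeric(0), amp = numeric(0))
  } else {
    ep <- as.data.frame(ep)
    if (!all(c("t_start", "t_end") %in% names(ep)))
      stop("`freeze_episodes` needs columns t_start and t_end", call. = FALSE)
    if (is.null(ep$freeze_freq)) ep$freeze_freq <- 5
    if (is.null(ep$amp)) ep$amp <- 3 * loco_amp
    ep <- ep[order(ep$t_start), , drop = FALSE]
    if (any(ep$t_end <= ep$t_start))
      stop("episodes must have t_end > t_start", call. = FALSE)
    if (any(ep$t_start < walk_interval[1]) || any(ep$t_end > walk_interval[2]))
      stop("episodes must lie inside the walk interval", call. = FALSE)
    if (nrow(ep) > 1L && any(ep$t_start[-1] < ep$t_end[-nrow(ep)]))
      stop("freeze episodes must not overlap", call. = FALSE)
    if (any(ep$freeze_freq < 3 | ep$freeze_freq > 8))
      stop("`freeze_freq` must lie in the 3-8 Hz freeze band", call. = FALSE)
  }
  set.seed(seed)
  t <- seq(0, duration, by = 1 / fs)
  walking <- t >= walk_interval[1] & t <= walk_interval[2]
  x <- ifelse(walking, loco_amp * sin(2 * pi * loco_freq * t), 0)
  for (j in seq_len(nrow(ep))) {
    in_ep <- t >= ep$t_start[j] & t < ep$t_end[j]
    tremble <- ep$amp[j] * sin(2 * pi * ep$freeze_freq[j] * t[in_ep])
    x[in_ep] <- if (additive) x[in_ep] + tremble else tremble
  }
  x <- x + stats::rnorm(length(t), 0, noise_sd)
  series <- uniform_ts(x, fs = fs, t0 = 0, label = "acc_vertical",
                       units = "m/s^2")
  truth <- list(episodes = ep[, c("t_start", "t_end", "freeze_freq", "amp")],
                total_freeze_time = sum(ep$t_end - ep$t_start),
                walk_interval = walk_interval,
                gait_time = diff(walk_interval), seed = seed)
  if (!is.null(out_prefix)) {
    side <- c(list(paradigm = "walk", fs = fs, units = "m/s^2",
                   walk_start = walk_interval[1], walk_stop = walk_interval[2],
                   seed = seed), meta)
    write_trial_csv(paste0(out_prefix, ".csv"),
                    data.frame(time = t, acc_vertical = x), side)
    jsonlite::write_json(truth, paste0(out_prefix, "_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(series = series, truth = truth)
}

#' Synthetic step-initiation trial
#'
#' Emulates the two channels of a step-initiation trial with known
#' onsets. The mediolateral force rests at a noisy zero baseline, rises
#' abruptly (half-cosine over `apa_rise`) to `apa_peak` at `apa_onset`,
#' holds through the step, and releases afterwards. The anteroposterior
#' foot displacement rises (half-cosine over `step_rise`) from
#' `step_onset` to `step_amp`. Ground truth records both onsets, the APA
#' duration and the normalized peak amplitude.
#'
#' @param duration trial length (s), default 6.
#' @param fs sampling rate (Hz), default 200.
#' @param apa_onset APA onset time (s), default 2.5.
#' @param apa_peak peak mediolateral force deviation (N), default 35.
#' @param apa_rise force rise time (s), default 0.05 (the APA load shift
#'   onsets abruptly).
#' @param step_onset step onset time (s), default 3.05 (truth APA
#'   duration 0.55 s); must exceed `apa_onset`.
#' @param step_amp foot displacement amplitude (cm), default 30.
#' @param step_rise displacement rise time (s), default 0.3.
#' @param noise_sd_force force channel noise SD (N); default 5% of
#'   `apa_peak`.
#' @param noise_sd_disp displacement channel noise SD (cm), default 0.1
#'   (marker precision).
#' @param foot_length foot length (cm), default 26.
#' @param stepping_side `"left"` or `"right"`.
#' @param release_after,release_time hold time after the step onset and
#'   force release duration (s).
#' @param seed RNG seed.
#' @param out_prefix optional path prefix for `<prefix>.csv`,
#'   `<prefix>.json`, `<prefix>_truth.json`.
#' @param meta optional named list merged into the sidecar metadata.
#' @return List with `trial` (a [step_trial()]) and `truth`.
#' @export
gen_step_trial <- function(duration = 6, fs = 200, apa_onset = 2.5,
                           apa_peak = 35, apa_rise = 0.05,
                           step_onset = 3.05, step_amp = 30,
                           step_rise = 0.3,
                           noise_sd_force = 0.05 * apa_peak,
                           noise_sd_disp = 0.1, foot_length = 26,
                           stepping_side = "left",
                           release_after = 0.3, release_time = 0.5,
                           seed = 1, out_prefix = NULL, meta = list()) {
  if (step_onset <= apa_onset)
    stop("`step_onset` must come after `apa_onset`", call. = FALSE)
  if (apa_onset < 1.2)
    stop("`apa_onset` must leave at least the 1 s quiet baseline", call. = FALSE)
  if (step_onset + step_rise > duration)
    stop("trial too short for the step", call. = FALSE)
  half_cos <- function(tau, rise) {
    y <- numeric(length(tau))
    up <- tau > 0 & tau < rise
    y[up] <- 0.5 * (1 - cos(pi * tau[up] / rise))
    y[tau >= rise] <- 1
    y
  }
  set.seed(seed)
  t <- seq(0, duration, by = 1 / fs)
  ml <- apa_peak * half_cos(t - apa_onset, apa_rise)
  rel_start <- step_onset + release_after
  ml <- ml * (1 - half_cos(t - rel_start, release_time))
  disp <- step_amp * half_cos(t - step_onset, step_rise)
  ml <- ml + stats::rnorm(length(t), 0, noise_sd_force)
  disp <- disp + stats::rnorm(length(t), 0, noise_sd_disp)
  trial <- step_trial(
    ml_force = uniform_ts(ml, fs = fs, t0 = 0, label = "ml_force", units = "N"),
    ap_foot_disp = uniform_ts(disp, fs = fs, t0 = 0, label = "ap_foot_disp",
                              units = "cm"),
    foot_length = foot_length, baseline_interval = c(0, 1),
    stepping_side = stepping_side)
  truth <- list(apa_onset = apa_onset, step_onset = step_onset,
                apa_duration = step_onset - apa_onset,
                apa_peak_amplitude = apa_peak / foot_length,
                foot_length = foot_length, seed = seed)
  if (!is.null(out_prefix)) {
    side <- c(list(paradigm = "step", fs = fs, foot_length_cm = foot_length,
                   stepping_side = stepping_side,
                   baseline_interval = c(0, 1), seed = seed), meta)
    write_trial_csv(paste0(out_prefix, ".csv"),
                    data.frame(time = t, ml_force = ml, ap_foot_disp = disp),
                    side)
    jsonlite::write_json(truth, paste0(out_prefix, "_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(trial = trial, truth = truth)
}

#' Block of synthetic step-initiation trials
#'
#' Convenience wrapper writing a block of `n` step trials (the protocol
#' uses a block of 10 per condition) to `out_dir`, one CSV + sidecar +
#' truth file per trial, with per-trial derived seeds.
#'
#' @param n number of trials (default 10).
#' @param out_dir output directory (created if needed).
#' @param seed base seed; trial `i` uses a seed derived from it.
#' @param prefix file-name prefix (default `"step"`).
#' @param ... passed on to [gen_step_trial()].
#' @return Invisibly, the vector of CSV paths written.
#' @export
gen_step_block <- function(n = 10, out_dir, seed = 1, prefix = "step", ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(n)
  for (i in seq_len(n)) {
    pre <- file.path(out_dir, sprintf("%s_%02d", prefix, i))
    gen_step_trial(..., seed = derive_seed(seed, i), out_prefix = pre)
    paths[i] <- paste0(pre, ".csv")
  }
  invisible(paths)
}

#' Synthetic support-surface perturbation trial
#'
#' Drives the five sagittal markers through a backward platform
#' translation plus a damped-oscillator body-sway response, and
#' constructs the six force-plate channels by inverse statics so that the
#' center of pressure of the generated record equals a known target
#' trajectory. The sway model is the minimal second-order system
#' producing plausible COM responses (relative sway `r` obeys
#' `r'' + 2*zeta*w*r' + w^2 r = -platform acceleration`); its parameters
#' are documented, not claimed physiological. Markers share the platform
#' translation plus height-scaled sway; the COP target follows the
#' inverted-pendulum relation `COP = COM - (h/g) * COM''`.
#'
#' @param duration trial length (s), default 8.
#' @param fs sampling rate (Hz), default 200.
#' @param amplitude,peak_velocity,peak_acceleration platform protocol
#'   parameters (defaults 12 cm, 15 cm/s, 100 cm/s^2).
#' @param preparatory_interval `c(min, max)` (s) of the random quiet
#'   interval preceding the perturbation (default 1--3 s, drawn
#'   uniformly) when `onset` is not given.
#' @param onset optional fixed perturbation onset (s).
#' @param sway_gain shoulder-level sway per unit relative oscillator
#'   displacement (dimensionless, default 0.25).
#' @param sway_freq oscillator natural frequency (Hz), default 1.
#' @param sway_damping damping ratio, default 0.3.
#' @param noise_sd marker measurement noise SD (cm), default 0.05.
#' @param body_mass subject mass (kg), default 75, sets Fz.
#' @param pendulum_height COM height (m) in the COP target relation,
#'   default 1.
#' @param marker_rest named rest AP positions (cm) of the five markers.
#' @param seed RNG seed.
#' @param out_prefix optional path prefix for CSV/sidecar/truth files.
#' @param meta optional named list merged into the sidecar metadata.
#' @return List with `trial` (a [perturbation_trial()]), `platform`
#'   (the displacement profile) and `truth` (onset plus noiseless COM/COP
#'   RMS over the analysis window).
#' @export
gen_perturbation_trial <- function(duration = 8, fs = 200, amplitude = 12,
                                   peak_velocity = 15, peak_acceleration = 100,
                                   preparatory_interval = c(1, 3),
                                   onset = NULL, sway_gain = 0.25,
                                   sway_freq = 1, sway_damping = 0.3,
                                   noise_sd = 0.05, body_mass = 75,
                                   pendulum_height = 1,
                                   marker_rest = c(meta5 = 14, malleolus = 6,
                                                   knee = 8, trochanter = 4,
                                                   shoulder = 2),
                                   seed = 1, out_prefix = NULL, meta = list()) {
  set.seed(seed)
  if (is.null(onset))
    onset <- stats::runif(1, preparatory_interval[1], preparatory_interval[2])
  analysis_window <- 2.5
  if (onset + analysis_window > duration)
    stop("trial too short for the post-perturbation analysis window", call. = FALSE)
  platform <- gen_platform_profile(amplitude, peak_velocity, peak_acceleration,
                                   fs = fs, onset = onset,
                                   total_duration = duration, direction = -1)
  p <- platform$values
  n <- length(p)
  t <- ts_time(platform)
  # platform acceleration by finite differences (cm/s^2)
  vel <- c(0, diff(p)) * fs
  acc <- c(0, diff(vel)) * fs
  # relative sway of the body on the moving base: damped oscillator
  w <- 2 * pi * sway_freq
  z <- sway_damping
  r <- numeric(n)
  dr <- 0
  for (i in 2:n) {
    ddr <- -acc[i] - 2 * z * w * dr - w^2 * r[i - 1]
    dr <- dr + ddr / fs
    r[i] <- r[i - 1] + dr / fs
  }
  sway_top <- sway_gain * r # shoulder-level sway (cm)
  heights <- c(meta5 = 0.02, malleolus = 0.08, knee = 0.47,
               trochanter = 0.92, shoulder = 1.45) # marker heights (m)
  mk_clean <- lapply(names(marker_rest), function(nm) {
    marker_rest[[nm]] + p + (heights[[nm]] / heights[["shoulder"]]) * sway_top
  })
  names(mk_clean) <- names(marker_rest)
  mk_noisy <- lapply(mk_clean, function(x) x + stats::rnorm(n, 0, noise_sd))
  as_uts <- function(x, lab, un) uniform_ts(x, fs = fs, t0 = 0, label = lab, units = un)
  markers <- do.call(marker_set, lapply(names(mk_noisy), function(nm)
    as_uts(mk_noisy[[nm]], nm, "cm")))

  model <- winter_model()
  com_clean <- com_ap(do.call(marker_set, lapply(names(mk_clean), function(nm)
    as_uts(mk_clean[[nm]], nm, "cm"))), model)$values
  # COP target: inverted-pendulum lead over the COM
  com_vel <- c(0, diff(com_clean)) * fs
  com_acc <- c(0, diff(com_vel)) * fs
  g_cm <- 980.665
  cop_target <- com_clean - (pendulum_height * 100 / g_cm) * com_acc

  fz <- rep(body_mass * 9.80665, n)
  fx <- body_mass * com_acc / 100 # N, horizontal shear tracking the COM
  my <- -(cop_target / 100) * fz # origin offsets zero
  tiny <- function() stats::rnorm(n, 0, 1e-3)
  plate <- force_plate_record(
    Fx = as_uts(fx, "Fx", "N"), Fy = as_uts(tiny(), "Fy", "N"),
    Fz = as_uts(fz, "Fz", "N"), Mx = as_uts(tiny(), "Mx", "N m"),
    My = as_uts(my, "My", "N m"), Mz = as_uts(tiny(), "Mz", "N m"),
    origin_offset = c(0, 0, 0))
  trial <- perturbation_trial(markers, plate, perturbation_onset = onset,
                              analysis_window = analysis_window)

  ref_idx <- idx_in_interval(t, onset - 1, onset)
  win_idx <- idx_in_interval(t, onset, onset + analysis_window)
  rms_about_ref <- function(x)
    sqrt(mean((x[win_idx] - mean(x[ref_idx]))^2))
  truth <- list(onset = onset, analysis_window = analysis_window,
                rms_com_ap = rms_about_ref(com_clean),
                rms_cop_ap = rms_about_ref(cop_target),
                sway_gain = sway_gain, seed = seed)
  if (!is.null(out_prefix)) {
    df <- data.frame(time = t, Fx = fx, Fy = plate$Fy$values, Fz = fz,
                     Mx = plate$Mx$values, My = my, Mz = plate$Mz$values,
                     meta5_ap = mk_noisy$meta5, malleolus_ap = mk_noisy$malleolus,
                     knee_ap = mk_noisy$knee, trochanter_ap = mk_noisy$trochanter,
                     shoulder_ap = mk_noisy$shoulder)
    side <- c(list(paradigm = "perturb", fs = fs, perturbation_onset = onset,
                   analysis_window = analysis_window,
                   origin_offset = c(0, 0, 0), seed = seed), meta)
    write_trial_csv(paste0(out_prefix, ".csv"), df, side)
    jsonlite::write_json(truth, paste0(out_prefix, "_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(trial = trial, platform = platform, truth = truth)
}

#' Generate a complete synthetic study
#'
#' Writes a full study tree -- subjects by stimulation conditions (OFF,
#' 60 Hz, 300 Hz) by paradigms -- of synthetic trials with ground truth,
#' in the same CSV + sidecar dialect the analysis pipeline reads:
#' `out_dir/S01/OFF/walk_01.csv` and so on. Condition effects emulate the
#' study's qualitative findings: high-frequency stimulation shortens
#' freezing and gait time, shortens APA duration and raises APA
#' amplitude, while reactive sway is unchanged; two of every four
#' subjects never freeze. Subject- and trial-level log-normal jitter is
#' seeded, so the same seed reproduces the tree byte for byte.
#'
#' @param out_dir output directory (created).
#' @param seed base seed; every trial derives its own seed from it.
#' @param n_subjects number of subjects (default 4).
#' @param conditions condition labels, default `c("OFF","HZ60","HZ300")`.
#' @param walk_trials,step_trials,perturb_trials trials per paradigm and
#'   condition (defaults 3, 10, 3, the protocol counts).
#' @return Invisibly, a data frame listing every file written (subject,
#'   condition, paradigm, path).
#' @export
simulate_study <- function(out_dir, seed = 1, n_subjects = 4,
                           conditions = c("OFF", "HZ60", "HZ300"),
                           walk_trials = 3, step_trials = 10,
                           perturb_trials = 3) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  eff <- list(
    OFF = list(apa_dur = 0.65, apa_peak = 32, freeze_len = 8.0, gait = 16.0),
    HZ60 = list(apa_dur = 0.66, apa_peak = 33, freeze_len = 7.5, gait = 15.5),
    HZ300 = list(apa_dur = 0.50, apa_peak = 37, freeze_len = 3.5, gait = 13.0))
  for (cc in conditions)
    if (is.null(eff[[cc]])) stop("unknown condition label: ", cc, call. = FALSE)
  set.seed(seed)
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  freezer <- (seq_len(n_subjects) %% 4L) %in% c(2L, 3L)
  subj_scale <- exp(stats::rnorm(n_subjects, 0, 0.08))
  foot <- round(stats::runif(n_subjects, 24, 29), 1)
  manifest <- list()
  counter <- 0L
  for (si in seq_len(n_subjects)) {
    for (cc in conditions) {
      cdir <- file.path(out_dir, subjects[si], cc)
      dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
      e <- eff[[cc]]
      for (k in seq_len(walk_trials)) {
        counter <- counter + 1L
        ts <- derive_seed(seed, counter)
        set.seed(ts)
        gait <- e$gait * subj_scale[si] * exp(stats::rnorm(1, 0, 0.04))
        dur <- ceiling(gait + 4)
        wi <- c(1.5, 1.5 + gait)
        ep <- NULL
        if (freezer[si]) {
          len <- max(2, e$freeze_len * exp(stats::rnorm(1, 0, 0.06)))
          len <- min(len, gait - 2)
          mid <- wi[1] + gait / 2
          ep <- data.frame(t_start = mid - len / 2, t_end = mid + len / 2,
                           freeze_freq = stats::runif(1, 4.5, 6), amp = 3)
        }
        pre <- file.path(cdir, sprintf("walk_%02d", k))
        gen_walk_trial(duration = dur, freeze_episodes = ep, walk_interval = wi,
                       seed = derive_seed(ts, 1), out_prefix = pre,
                       meta = list(subject = subjects[si], condition = cc))
        manifest[[length(manifest) + 1L]] <- data.frame(
          subject = subjects[si], condition = cc, paradigm = "walk",
          path = paste0(pre, ".csv"), stringsAsFactors = FALSE)
      }
      for (k in seq_len(step_trials)) {
        counter <- counter + 1L
        ts <- derive_seed(seed, counter)
        set.seed(ts)
        dur_apa <- e$apa_dur * subj_scale[si] * exp(stats::rnorm(1, 0, 0.05))
        peak <- e$apa_peak * subj_scale[si] * exp(stats::rnorm(1, 0, 0.05))
        a_on <- stats::runif(1, 2.2, 2.8)
        pre <- file.path(cdir, sprintf("step_%02d", k))
        gen_step_trial(apa_onset = a_on, step_onset = a_on + dur_apa,
                       apa_peak = peak, foot_length = foot[si],
                       seed = derive_seed(ts, 1), out_prefix = pre,
                       meta = list(subject = subjects[si], condition = cc))
        manifest[[length(manifest) + 1L]] <- data.frame(
          subject = subjects[si], condition = cc, paradigm = "step",
          path = paste0(pre, ".csv"), stringsAsFactors = FALSE)
      }
      for (k in seq_len(perturb_trials)) {
        counter <- counter + 1L
        ts <- derive_seed(seed, counter)
        set.seed(ts)
        gain <- 0.25 * subj_scale[si] * exp(stats::rnorm(1, 0, 0.05))
        pre <- file.path(cdir, sprintf("perturb_%02d", k))
        gen_perturbation_trial(sway_gain = gain, seed = derive_seed(ts, 1),
                               out_prefix = pre,
                               meta = list(subject = subjects[si], condition = cc))
        manifest[[length(manifest) + 1L]] <- data.frame(
          subject = subjects[si], condition = cc, paradigm = "perturb",
          path = paste0(pre, ".csv"), stringsAsFactors = FALSE)
      }
    }
  }
  invisible(do.call(rbind, manifest))
}
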