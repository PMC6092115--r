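# Trial file dialect: a CSV with a `time` column plus one column per
# channel, and a JSON sidecar (same path, .json) with fs, units and
# paradigm metadata. Decimal point, UTF-8, no thousands separators.
# Readers reject non-finite cells.

sidecar_path <- function(csv_path) sub("\\.csv$", ".json", csv_path)

write_trial_csv <- function(path, df, sidecar) {
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_trial_table <- function(csv_path) {
  if (!file.exists(csv_path)) stop("no such trial file: ", csv_path, call. = FALSE)
  df <- utils::read.csv(csv_path)
  if (!"time" %in% names(df)) stop(csv_path, ": missing `time` column", call. = FALSE)
  for (nm in names(df))
    if (!all(is.finite(df[[nm]])))
      stop(csv_path, ": non-finite values in column ", nm, call. = FALSE)
  side_path <- sidecar_path(csv_path)
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path,
                                                          simplifyVector = TRUE)
          else list()
  list(data = df, meta = side)
}

col_uts <- function(df, col, fs, units = "") {
  if (!col %in% names(df)) stop("missing column ", col, call. = FALSE)
  uniform_ts(df[[col]], fs = fs, t0 = df$time[1], label = col, units = units)
}

#' Read a walking trial from CSV + sidecar
#'
#' Expects columns `time, acc_vertical` and a JSON sidecar carrying at
#' least `fs`, optionally `walk_start`/`walk_stop` marks and subject /
#' condition labels.
#'
#' @param csv_path path to the trial CSV.
#' @return List with `series` (a [uniform_ts()]), `marks` (or `NULL`)
#'   and `meta` (the sidecar contents).
#' @export
read_walk_trial <- function(csv_path) {
  tr <- read_trial_table(csv_path)
  fs <- tr$meta$fs %||% (1 / stats::median(diff(tr$data$time)))
  series <- col_uts(tr$data, "acc_vertical", fs, tr$meta$units %||% "m/s^2")
  marks <- if (!is.null(tr$meta$walk_start) && !is.null(tr$meta$walk_stop))
    c(tr$meta$walk_start, tr$meta$walk_stop) else NULL
  list(series = series, marks = marks, meta = tr$meta)
}

#' Read a step-initiation trial from CSV + sidecar
#'
#' Expects columns `time, ml_force, ap_foot_disp` and a sidecar with
#' `fs`, `foot_length_cm`, and optionally `stepping_side` and
#' `baseline_interval`.
#'
#' @param csv_path path to the trial CSV.
#' @return List with `trial` (a [step_trial()]) and `meta`.
#' @export
read_step_trial <- function(csv_path) {
  tr <- read_trial_table(csv_path)
  fs <- tr$meta$fs %||% (1 / stats::median(diff(tr$data$time)))
  if (is.null(tr$meta$foot_length_cm))
    stop(csv_path, ": sidecar must provide foot_length_cm", call. = FALSE)
  trial <- step_trial(
    ml_force = col_uts(tr$data, "ml_force", fs, "N"),
    ap_foot_disp = col_uts(tr$data, "ap_foot_disp", fs, "cm"),
    foot_length = tr$meta$foot_length_cm,
    baseline_interval = tr$meta$baseline_interval %||% NULL,
    stepping_side = tr$meta$stepping_side %||% "left")
  list(trial = trial, meta = tr$meta)
}

#' Read a perturbation trial from CSV + sidecar
#'
#' Expects the six plate channels `Fx..Mz` and the five marker columns
#' `meta5_ap, malleolus_ap, knee_ap, trochanter_ap, shoulder_ap`, plus a
#' sidecar with `fs`, `perturbation_onset` and optionally
#' `origin_offset` and `analysis_window`.
#'
#' @param csv_path path to the trial CSV.
#' @return List with `trial` (a [perturbation_trial()]) and `meta`.
#' @export
read_perturbation_trial <- function(csv_path) {
  tr <- read_trial_table(csv_path)
  fs <- tr$meta$fs %||% (1 / stats::median(diff(tr$data$time)))
  if (is.null(tr$meta$perturbation_onset))
    stop(csv_path, ": sidecar must provide perturbation_onset", call. = FALSE)
  plate <- force_plate_record(
    Fx = col_uts(tr$data, "Fx", fs, "N"), Fy = col_uts(tr$data, "Fy", fs, "N"),
    Fz = col_uts(tr$data, "Fz", fs, "N"),
    Mx = col_uts(tr$data, "Mx", fs, "N m"),
    My = col_uts(tr$data, "My", fs, "N m"),
    Mz = col_uts(tr$data, "Mz", fs, "N m"),
    origin_offset = tr$meta$origin_offset %||% c(0, 0, 0))
  markers <- marker_set(
    meta5 = col_uts(tr$data, "meta5_ap", fs, "cm"),
    malleolus = col_uts(tr$data, "malleolus_ap", fs, "cm"),
    knee = col_uts(tr$data, "knee_ap", fs, "cm"),
    trochanter = col_uts(tr$data, "trochanter_ap", fs, "cm"),
    shoulder = col_uts(tr$data, "shoulder_ap", fs, "cm"))
  trial <- perturbation_trial(markers, plate,
                              perturbation_onset = tr$meta$perturbation_onset,
                              analysis_window = tr$meta$analysis_window %||% 2.5)
  list(trial = trial, meta = tr$meta)
}
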