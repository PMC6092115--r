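#' Study configuration
#'
#' Collects the inputs and analysis parameters of a full study run. All
#' protocol defaults (band edges, 7.5 s spectral span, freeze threshold
#' 2, 10 Hz dual-pass filter, 2-SD onset multiplier, analysis windows)
#' live here so the operative parameters are visible in one place. A
#' configuration can also be read from YAML with
#' [study_config_from_yaml()].
#'
#' The input directory must be laid out as
#' `input_dir/<subject>/<condition>/<paradigm>_<nn>.csv` with JSON
#' sidecars, the layout [simulate_study()] writes. Paradigms are
#' recognized by file-name prefix: `walk`, `step`, `perturb`.
#'
#' @param input_dir directory of trial files.
#' @param output_dir directory for result files (created).
#' @param bands a [band_spec()].
#' @param span,hop spectral window length and stride (s).
#' @param filter a [filter_spec()] used for all low-pass filtering.
#' @param k onset-detection threshold multiplier (default 2).
#' @param min_hold onset sustained-crossing requirement (s).
#' @param analysis_window post-perturbation window (s).
#' @param model an [anthro_model()] for COM estimation.
#' @param baseline,on_conditions condition labels.
#' @param alpha significance level.
#' @return An object of class `study_config`.
#' @export
study_config <- function(input_dir, output_dir,
                         bands = band_spec(), span = 7.5, hop = 0.25,
                         filter = filter_spec(10, 2), k = 2, min_hold = 0.05,
                         analysis_window = 2.5, model = winter_model(),
                         baseline = "OFF", on_conditions = c("HZ60", "HZ300"),
                         alpha = 0.05) {
  if (!dir.exists(input_dir))
    stop("input directory does not exist: ", input_dir, call. = FALSE)
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 bands = bands, span = span, hop = hop, filter = filter,
                 k = k, min_hold = min_hold,
                 analysis_window = analysis_window, model = model,
                 baseline = baseline, on_conditions = on_conditions,
                 alpha = alpha),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Recognized keys: `input_dir`, `output_dir`, `loco_band`,
#' `freeze_band`, `fog_threshold`, `span`, `hop`, `cutoff_hz`,
#' `filter_order_per_pass`, `k`, `min_hold`, `analysis_window`,
#' `baseline`, `on_conditions`, `alpha`. Missing keys take the
#' [study_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
study_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$input_dir) || is.null(y$output_dir))
    stop("YAML config must provide input_dir and output_dir", call. = FALSE)
  study_config(
    input_dir = y$input_dir, output_dir = y$output_dir,
    bands = band_spec(loco_band = unlist(y$loco_band) %||% c(0.5, 3),
                      freeze_band = unlist(y$freeze_band) %||% c(3, 8),
                      threshold = y$fog_threshold %||% 2),
    span = y$span %||% 7.5, hop = y$hop %||% 0.25,
    filter = filter_spec(y$cutoff_hz %||% 10, y$filter_order_per_pass %||% 2),
    k = y$k %||% 2, min_hold = y$min_hold %||% 0.05,
    analysis_window = y$analysis_window %||% 2.5,
    baseline = y$baseline %||% "OFF",
    on_conditions = unlist(y$on_conditions) %||% c("HZ60", "HZ300"),
    alpha = y$alpha %||% 0.05)
}

analyze_one_trial <- function(path, paradigm, config) {
  if (paradigm == "walk") {
    tr <- read_walk_trial(path)
    fog <- detect_fog(tr$series, bands = config$bands, span = config$span,
                      hop = config$hop, prefilter = config$filter,
                      marks = tr$marks)
    data.frame(variable = c("gait_time", "fog_time"),
               value = c(fog$gait_time, fog$total_fog_time),
               stringsAsFactors = FALSE)
  } else if (paradigm == "step") {
    tr <- read_step_trial(path)
    m <- apa_metrics(tr$trial, k = config$k, min_hold = config$min_hold)
    if (!m$valid) stop("invalid step trial: ", m$note, call. = FALSE)
    data.frame(variable = c("apa_duration", "apa_amplitude"),
               value = c(m$apa_duration, m$apa_peak_amplitude),
               stringsAsFactors = FALSE)
  } else if (paradigm == "perturb") {
    tr <- read_perturbation_trial(path)
    tr$trial$analysis_window <- config$analysis_window
    m <- reactive_metrics(tr$trial, model = config$model,
                          filter = config$filter)
    data.frame(variable = c("cop_ap_rms", "com_ap_rms"),
               value = c(m$rms_cop_ap, m$rms_com_ap),
               stringsAsFactors = FALSE)
  } else {
    stop("unknown paradigm: ", paradigm, call. = FALSE)
  }
}

#' Run a full study analysis
#'
#' Walks the input tree, analyzes every trial (freeze detection on walk
#' trials, APA metrics on step trials, reactive-posture metrics on
#' perturbation trials), aggregates the results with
#' [summarize_study()], and writes `trial_metrics.tsv`, `summary.tsv`,
#' `percent_change.tsv`, `ttests.json` and a `manifest.json` recording
#' parameters, package version, and the status of every trial. A
#' malformed trial is logged and skipped; only configuration errors
#' (e.g. an empty input tree) abort the run. Outputs are a pure function
#' of the input files and the configuration, so a rerun with the same
#' inputs is byte-identical.
#'
#' @param config a [study_config()], or the path of a YAML config file.
#' @return Invisibly, a list with `metrics` (the per-trial long table),
#'   `results` (the [summarize_study()] output) and `manifest`.
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- study_config_from_yaml(config)
  stopifnot(inherits(config, "study_config"))
  subjects <- sort(list.dirs(config$input_dir, recursive = FALSE,
                             full.names = FALSE))
  rows <- list()
  log <- list()
  for (s in subjects) {
    conds <- sort(list.dirs(file.path(config$input_dir, s), recursive = FALSE,
                            full.names = FALSE))
    for (cc in conds) {
      files <- sort(list.files(file.path(config$input_dir, s, cc),
                               pattern = "^(walk|step|perturb)_.*\\.csv$",
                               full.names = TRUE))
      for (f in files) {
        paradigm <- sub("_.*$", "", basename(f))
        res <- tryCatch(analyze_one_trial(f, paradigm, config),
                        error = function(e) e)
        if (inherits(res, "error")) {
          log[[length(log) + 1L]] <- data.frame(
            subject = s, condition = cc, paradigm = paradigm,
            file = basename(f), status = "skipped",
            note = conditionMessage(res), stringsAsFactors = FALSE)
        } else {
          res$subject <- s
          res$condition <- cc
          res$trial <- basename(f)
          rows[[length(rows) + 1L]] <- res
          log[[length(log) + 1L]] <- data.frame(
            subject = s, condition = cc, paradigm = paradigm,
            file = basename(f), status = "ok", note = "",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    stop("no analyzable trials found under ", config$input_dir, call. = FALSE)
  metrics <- do.call(rbind, rows)
  metrics <- metrics[, c("subject", "condition", "trial", "variable", "value")]
  results <- suppressMessages(
    summarize_study(metrics, baseline = config$baseline,
                    on_conditions = config$on_conditions,
                    alpha = config$alpha))
  log <- do.call(rbind, log)

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, name)
    utils::write.table(df, file.path(config$output_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  wtsv(metrics, "trial_metrics.tsv")
  wtsv(results$summary, "summary.tsv")
  wtsv(results$percent_change, "percent_change.tsv")
  jsonlite::write_json(results$ttests,
                       file.path(config$output_dir, "ttests.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  manifest <- list(
    package = "pfk",
    version = as.character(utils::packageVersion("pfk")),
    parameters = list(
      loco_band = config$bands$loco_band,
      freeze_band = config$bands$freeze_band,
      fog_threshold = config$bands$threshold,
      span = config$span, hop = config$hop,
      cutoff_hz = config$filter$cutoff,
      filter_order_per_pass = config$filter$order_per_pass,
      k = config$k, min_hold = config$min_hold,
      analysis_window = config$analysis_window,
      baseline = config$baseline, on_conditions = config$on_conditions,
      alpha = config$alpha),
    n_trials = nrow(log), n_skipped = sum(log$status == "skipped"),
    trials = log)
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(metrics = metrics, results = results, manifest = manifest))
}
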