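#' Force-plate record (six channels)
#'
#' Forces (N) and moments (N m) about the plate origin. Axis convention:
#' x = anteroposterior (positive forward), y = mediolateral, z = vertical
#' (Fz positive under load). `origin_offset` is the plate-origin offset
#' `c(ap, ml, vertical)` in meters, for plates whose geometric origin is
#' not at the surface reference point.
#'
#' @param Fx,Fy,Fz force channels (N), [uniform_ts()] objects.
#' @param Mx,My,Mz moment channels (N m), [uniform_ts()] objects.
#' @param origin_offset numeric length-3 `c(ap, ml, vertical)` in m.
#' @return An object of class `force_plate_record`.
#' @export
force_plate_record <- function(Fx, Fy, Fz, Mx, My, Mz,
                               origin_offset = c(0, 0, 0)) {
  chans <- list(Fx = Fx, Fy = Fy, Fz = Fz, Mx = Mx, My = My, Mz = Mz)
  for (nm in names(chans))
    if (!inherits(chans[[nm]], "uniform_ts"))
      stop(sprintf("channel %s must be a uniform_ts", nm), call. = FALSE)
  fs <- vapply(chans, function(s) s$fs, numeric(1))
  n <- vapply(chans, function(s) length(s$values), numeric(1))
  if (length(unique(fs)) != 1L || length(unique(n)) != 1L)
    stop("all six plate channels must share fs and length", call. = FALSE)
  if (length(origin_offset) != 3L)
    stop("`origin_offset` must be c(ap, ml, vertical) in m", call. = FALSE)
  structure(c(chans, list(origin_offset = as.numeric(origin_offset))),
            class = "force_plate_record")
}

#' Sagittal marker set for center-of-mass estimation
#'
#' Anteroposterior coordinate series (cm) of the five sagittal markers
#' used by the segmental model: fifth metatarsophalangeal joint, lateral
#' malleolus, lateral knee joint center, greater trochanter, and the
#' approximate axis of shoulder rotation. One hemibody's markers stand in
#' for both sides (symmetric-displacement assumption).
#'
#' @param meta5,malleolus,knee,trochanter,shoulder AP-coordinate series
#'   (cm), [uniform_ts()] objects sharing fs and length.
#' @return An object of class `marker_set`.
#' @export
marker_set <- function(meta5, malleolus, knee, trochanter, shoulder) {
  m <- list(meta5 = meta5, malleolus = malleolus, knee = knee,
            trochanter = trochanter, shoulder = shoulder)
  for (nm in names(m))
    if (!inherits(m[[nm]], "uniform_ts"))
      stop(sprintf("marker %s must be a uniform_ts", nm), call. = FALSE)
  fs <- vapply(m, function(s) s$fs, numeric(1))
  n <- vapply(m, function(s) length(s$values), numeric(1))
  if (length(unique(fs)) != 1L || length(unique(n)) != 1L)
    stop("all markers must share fs and length", call. = FALSE)
  structure(m, class = "marker_set")
}

#' Segmental anthropometric model
#'
#' A table of body segments, each defined by a proximal and a distal
#' marker, its mass fraction of total body mass, the segment
#' center-of-mass location as a fraction of segment length from the
#' proximal end, and a count (2 for bilateral limb segments represented
#' by one hemibody's markers, 1 for axial segments). The mass fractions
#' weighted by count must sum to 1.
#'
#' @param segments data frame with columns `name`, `proximal`, `distal`,
#'   `mass_fraction`, `com_fraction`, `count`.
#' @return An object of class `anthro_model`.
#' @seealso [winter_model()] for the default segment table.
#' @export
anthro_model <- function(segments) {
  need <- c("name", "proximal", "distal", "mass_fraction", "com_fraction", "count")
  if (!is.data.frame(segments) || !all(need %in% names(segments)))
    stop("`segments` must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  tot <- sum(segments$mass_fraction * segments$count)
  if (abs(tot - 1) > 1e-6)
    stop(sprintf("segment mass fractions (weighted by count) sum to %.8f, not 1",
                 tot), call. = FALSE)
  if (any(segments$com_fraction < 0 | segments$com_fraction > 1))
    stop("`com_fraction` values must lie in [0, 1]", call. = FALSE)
  structure(list(segments = segments), class = "anthro_model")
}

#' Default segment table for sagittal COM estimation
#'
#' Standard segment mass and center-of-mass fractions for a four-segment
#' sagittal body model: foot (malleolus to fifth metatarsophalangeal,
#' mass 0.0145, COM at 0.50), shank (knee to malleolus, 0.0465/0.433),
#' thigh (trochanter to knee, 0.100/0.433), each counted twice for the
#' two body sides, and a single head-arms-trunk (HAT) segment from the
#' greater trochanter toward the shoulder axis (0.678, COM at 0.626).
#' Weighted fractions sum to 1. Override with [anthro_model()] to use a
#' different table.
#'
#' @return An `anthro_model`.
#' @export
winter_model <- function() {
  anthro_model(data.frame(
    name = c("foot", "shank", "thigh", "hat"),
    proximal = c("malleolus", "knee", "trochanter", "trochanter"),
    distal = c("meta5", "malleolus", "knee", "shoulder"),
    mass_fraction = c(0.0145, 0.0465, 0.100, 0.678),
    com_fraction = c(0.50, 0.433, 0.433, 0.626),
    count = c(2, 2, 2, 1),
    stringsAsFactors = FALSE))
}

#' Anteroposterior center of pressure from a force-plate record
#'
#' Plate statics: the AP coordinate of the point of application of the
#' ground-reaction force is
#' `COP_ap = -(My + Fx * dz) / Fz + d_ap`,
#' where `My` is the moment about the mediolateral axis and
#' `(d_ap, ., dz)` is the plate-origin offset. The result is returned in
#' cm. Statics are ill-conditioned at low vertical load, so every
#' analyzed sample must carry `|Fz| > fz_min`.
#'
#' @param plate a [force_plate_record()].
#' @param fz_min minimum vertical load in N (default 50).
#' @return `uniform_ts` of COP_ap in cm.
#' @export
cop_ap <- function(plate, fz_min = 50) {
  stopifnot(inherits(plate, "force_plate_record"))
  fz <- plate$Fz$values
  low <- which(abs(fz) <= fz_min)
  if (length(low)) {
    t <- ts_time(plate$Fz)
    stop(sprintf("vertical load |Fz| <= %g N at t = %.4f s; plate statics undefined",
                 fz_min, t[low[1]]), call. = FALSE)
  }
  off <- plate$origin_offset
  cop_m <- -(plate$My$values + plate$Fx$values * off[3]) / fz + off[1]
  uniform_ts(cop_m * 100, fs = plate$Fz$fs, t0 = plate$Fz$t0,
             label = "cop_ap", units = "cm")
}

#' Anteroposterior center of mass from sagittal markers
#'
#' Per sample, each segment's COM is
#' `proximal + com_fraction * (distal - proximal)`; the whole-body COM is
#' the count- and mass-fraction-weighted sum of segment COMs.
#'
#' @param markers a [marker_set()].
#' @param model an [anthro_model()]; default [winter_model()].
#' @return `uniform_ts` of COM_ap in cm.
#' @export
com_ap <- function(markers, model = winter_model()) {
  stopifnot(inherits(markers, "marker_set"), inherits(model, "anthro_model"))
  seg <- model$segments
  missing <- setdiff(unique(c(seg$proximal, seg$distal)), names(markers))
  if (length(missing))
    stop("model references markers absent from the set: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ref <- markers$malleolus
  com <- numeric(length(ref$values))
  for (j in seq_len(nrow(seg))) {
    p <- markers[[seg$proximal[j]]]$values
    d <- markers[[seg$distal[j]]]$values
    seg_com <- p + seg$com_fraction[j] * (d - p)
    com <- com + seg$count[j] * seg$mass_fraction[j] * seg_com
  }
  uniform_ts(com, fs = ref$fs, t0 = ref$t0, label = "com_ap", units = "cm")
}

#' Perturbation-trial container
#'
#' A support-surface translation trial: the five sagittal markers, the
#' force-plate record, the perturbation onset time, and the length of the
#' post-perturbation analysis window.
#'
#' @param markers a [marker_set()].
#' @param plate a [force_plate_record()].
#' @param perturbation_onset perturbation onset time (s), inside the
#'   recording.
#' @param analysis_window post-onset window length (s), default 2.5
#'   (the platform motion lasts under 1 s and recovery completes within
#'   2--3 s).
#' @return An object of class `perturbation_trial`.
#' @export
perturbation_trial <- function(markers, plate, perturbation_onset,
                               analysis_window = 2.5) {
  stopifnot(inherits(markers, "marker_set"), inherits(plate, "force_plate_record"))
  dur <- ts_duration(plate$Fz)
  t0 <- plate$Fz$t0
  if (perturbation_onset < t0 || perturbation_onset > t0 + dur)
    stop("perturbation onset lies outside the recording", call. = FALSE)
  if (analysis_window <= 0)
    stop("`analysis_window` must be positive", call. = FALSE)
  structure(list(markers = markers, plate = plate,
                 perturbation_onset = perturbation_onset,
                 analysis_window = analysis_window),
            class = "perturbation_trial")
}

#' Reactive-posture metrics of a perturbation trial
#'
#' Computes COP_ap (plate statics) and COM_ap (segmental model), low-pass
#' filters both (default 10 Hz dual-pass), references each to its own
#' mean over the 1 s of quiet stance immediately preceding the
#' perturbation onset, and returns the root-mean-square displacement of
#' each over the post-onset analysis window `[onset, onset + window)`.
#'
#' @param trial a [perturbation_trial()].
#' @param model an [anthro_model()]; default [winter_model()].
#' @param filter a [filter_spec()] applied to both series, or `NULL`.
#' @param fz_min minimum vertical load (N) for COP validity.
#' @param reference_window length (s) of the pre-onset referencing
#'   window (default 1).
#' @return Object of class `reactive_metrics`: list with `rms_com_ap`
#'   and `rms_cop_ap`, both in cm.
#' @export
reactive_metrics <- function(trial, model = winter_model(),
                             filter = filter_spec(10, 2), fz_min = 50,
                             reference_window = 1) {
  stopifnot(inherits(trial, "perturbation_trial"))
  onset <- trial$perturbation_onset
  win <- trial$analysis_window
  t0 <- trial$plate$Fz$t0
  dur <- ts_duration(trial$plate$Fz)
  if (onset + win > t0 + dur + 1e-9)
    stop("analysis window extends past the end of the recording", call. = FALSE)
  if (onset - reference_window < t0 - 1e-9)
    stop("not enough pre-perturbation recording for the reference window",
         call. = FALSE)
  cop <- cop_ap(trial$plate, fz_min = fz_min)
  com <- com_ap(trial$markers, model)
  if (!is.null(filter)) {
    cop <- butter_dual_pass(cop, filter)
    com <- butter_dual_pass(com, filter)
  }
  ref_int <- c(onset - reference_window, onset)
  ana_int <- c(onset, onset + win)
  one <- function(s) {
    ref <- baseline_stats(s, ref_int)$mean
    rms_displacement(s, ana_int, reference = ref)
  }
  structure(list(rms_com_ap = one(com), rms_cop_ap = one(cop)),
            class = "reactive_metrics")
}

#' @export
print.reactive_metrics <- function(x, ...) {
  cat(sprintf("<reactive_metrics> RMS COM_ap %.3f cm, RMS COP_ap %.3f cm\n",
              x$rms_com_ap, x$rms_cop_ap))
  invisible(x)
}
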