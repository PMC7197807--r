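ROI_LABELS <- c("St", "Th", "BFWB")

#' Gamma-scan schedule
#'
#' @param times_h strictly increasing positive scan times in hours; default
#'   the clinical one-week protocol of six whole-body scans at 1, 4, 24,
#'   48, 72 and 168 h after administration.
#' @return object of class `scan_schedule` with `times_h` and `n_scans`.
#' @export
scan_schedule <- function(times_h = c(1, 4, 24, 48, 72, 168)) {
  if (!is.numeric(times_h) || length(times_h) < 1L || anyNA(times_h) ||
      any(times_h <= 0) || is.unsorted(times_h, strictly = TRUE))
    stop_domain("schedule times must be strictly increasing and > 0")
  structure(list(times_h = as.numeric(times_h),
                 n_scans = length(times_h)),
            class = "scan_schedule")
}

#' Per-patient ROI time series
#'
#' Holds the three region-of-interest series measured on each scan:
#' `St` (stomach), `Th` (thyroid) and `BFWB` (body fluid + whole body),
#' plus an optional `BKG` background series. Values are count/pixel/s when
#' raw, dimensionless after [normalize_dataset()].
#'
#' @param patient_id label.
#' @param schedule a [scan_schedule()].
#' @param st,th,bfwb numeric series, one value per scan, all >= 0.
#' @param bkg optional background series (same length) for
#'   [subtract_background()].
#' @param normalized logical flag; if `TRUE` the first stomach value must
#'   equal 1 exactly.
#' @return object of class `measurement_set`.
#' @export
measurement_set <- function(patient_id, schedule, st, th, bfwb, bkg = NULL,
                            normalized = FALSE) {
  stopifnot(inherits(schedule, "scan_schedule"))
  series <- list(St = st, Th = th, BFWB = bfwb)
  for (roi in names(series)) {
    v <- series[[roi]]
    if (!is.numeric(v) || length(v) != schedule$n_scans || anyNA(v) ||
        any(v < 0))
      stop_domain("ROI ", roi, " must have ", schedule$n_scans,
                  " non-negative values")
    series[[roi]] <- as.numeric(v)
  }
  if (!is.null(bkg)) {
    if (!is.numeric(bkg) || length(bkg) != schedule$n_scans || anyNA(bkg) ||
        any(bkg < 0))
      stop_domain("BKG series must have ", schedule$n_scans,
                  " non-negative values")
    bkg <- as.numeric(bkg)
  }
  if (isTRUE(normalized) && series$St[1] != 1)
    stop_domain("a normalized dataset must have St = 1 at the first scan")
  structure(list(patient_id = patient_id, schedule = schedule,
                 series = series, bkg = bkg,
                 normalized = isTRUE(normalized)),
            class = "measurement_set")
}

#' Background-corrected count rate
#'
#' Subtracts the background ROI rate from a gross ROI rate, clamping the
#' net rate at zero (with a warning) when background exceeds signal.
#'
#' @param gross,background count/pixel/s, both >= 0; vectorized.
#' @return net count rate, same length.
#' @export
net_count_rate <- function(gross, background) {
  if (!is.numeric(gross) || !is.numeric(background) || anyNA(gross) ||
      anyNA(background) || any(gross < 0) || any(background < 0))
    stop_domain("gross and background rates must be non-negative")
  net <- gross - background
  if (any(net < 0)) {
    warning("background exceeds gross count rate; net rate clamped to 0",
            call. = FALSE)
    net[net < 0] <- 0
  }
  net
}

#' Subtract the background series from every ROI of a measurement set
#'
#' @param ms a raw [measurement_set()] carrying a `BKG` series; if no
#'   background was recorded the data are returned unchanged.
#' @return a raw `measurement_set` with background removed and no `BKG`.
#' @export
subtract_background <- function(ms) {
  stopifnot(inherits(ms, "measurement_set"))
  if (ms$normalized)
    stop_domain("background must be subtracted before normalization")
  if (is.null(ms$bkg)) return(ms)
  measurement_set(ms$patient_id, ms$schedule,
                  st   = net_count_rate(ms$series$St,   ms$bkg),
                  th   = net_count_rate(ms$series$Th,   ms$bkg),
                  bfwb = net_count_rate(ms$series$BFWB, ms$bkg))
}

#' Project a model trajectory onto the measured ROIs
#'
#' The planar-scan ROIs see: `St` = stomach compartment, `Th` = thyroid
#' compartment, `BFWB` = body fluid + whole body. The excretion compartment
#' (voided activity) is not in the field of view and is excluded.
#'
#' @param traj a `trajectory` from [solve_trajectory()] sampled exactly on
#'   `schedule$times_h`.
#' @param schedule a [scan_schedule()]; default reconstructed from the
#'   trajectory's own times.
#' @param patient_id label for the resulting set.
#' @return a raw (noise-free) [measurement_set()].
#' @export
project_observables <- function(traj, schedule = scan_schedule(traj$times_h),
                                patient_id = "model") {
  stopifnot(inherits(traj, "trajectory"), inherits(schedule, "scan_schedule"))
  if (length(traj$times_h) != schedule$n_scans ||
      any(abs(traj$times_h - schedule$times_h) > 1e-9))
    stop_domain("trajectory sampling times do not match the scan schedule")
  q <- traj$q
  measurement_set(patient_id, schedule,
                  st   = q[, "stomach"],
                  th   = q[, "thyroid"],
                  bfwb = q[, "bodyfluid"] + q[, "wholebody"])
}

#' Normalize a dataset to the first stomach value
#'
#' Every ROI value is divided by the stomach value at the first scan (the
#' maximal stomach reading, one hour after administration), which becomes
#' the dimensionless standard 1.0. Any detector gain common to all ROIs
#' cancels, making normalized data comparable with model predictions.
#' Idempotent.
#'
#' @param ms a [measurement_set()]; background, if present, is subtracted
#'   first via [subtract_background()].
#' @return a normalized `measurement_set`.
#' @export
normalize_dataset <- function(ms) {
  stopifnot(inherits(ms, "measurement_set"))
  if (ms$normalized) return(ms)
  ms <- subtract_background(ms)
  ref <- ms$series$St[1]
  if (!is.finite(ref) || ref <= 0)
    stop_domain("cannot normalize: stomach value at the first scan is ",
                ref, " (dataset unusable)")
  measurement_set(ms$patient_id, ms$schedule,
                  st   = ms$series$St / ref,
                  th   = ms$series$Th / ref,
                  bfwb = ms$series$BFWB / ref,
                  normalized = TRUE)
}

#' AT agreement index between two normalized series
#'
#' Root-mean-square deviation between observed and predicted normalized
#' intensities over the N scans:
#' `AT = sqrt( sum_i (Y_obs_i - Y_pred_i)^2 / N )`. Zero means perfect
#' agreement; the index has the same scale as the normalized intensities.
#'
#' @param observed,predicted numeric series of equal length N >= 1.
#' @return dimensionless AT value >= 0.
#' @export
at_index <- function(observed, predicted) {
  if (!is.numeric(observed) || !is.numeric(predicted) ||
      length(observed) != length(predicted) || length(observed) < 1L ||
      anyNA(observed) || anyNA(predicted))
    stop_domain("observed and predicted must be numeric series of equal ",
                "length >= 1")
  sqrt(mean((observed - predicted)^2))
}

#' Total AT over the three ROIs
#'
#' Root of the mean of the squared per-ROI AT values:
#' `AT_tot = sqrt((AT_St^2 + AT_Th^2 + AT_BFWB^2) / 3)`.
#'
#' @param at_st,at_th,at_bfwb per-ROI AT values, all >= 0.
#' @return dimensionless total AT.
#' @export
at_total <- function(at_st, at_th, at_bfwb) {
  v <- c(at_st, at_th, at_bfwb)
  if (!is.numeric(v) || length(v) != 3L || anyNA(v) || any(v < 0))
    stop_domain("AT components must be three non-negative numbers")
  sqrt(mean(v^2))
}

#' Full AT report for a pair of normalized measurement sets
#'
#' @param observed,predicted normalized [measurement_set()] objects on the
#'   same schedule (predicted is normalized first if raw).
#' @return object of class `at_report`: `at_st`, `at_th`, `at_bfwb`,
#'   `at_total`, `n`.
#' @export
at_report <- function(observed, predicted) {
  stopifnot(inherits(observed, "measurement_set"),
            inherits(predicted, "measurement_set"))
  if (!observed$normalized) observed <- normalize_dataset(observed)
  if (!predicted$normalized) predicted <- normalize_dataset(predicted)
  if (observed$schedule$n_scans != predicted$schedule$n_scans)
    stop_domain("observed and predicted are on different schedules")
  ats <- vapply(ROI_LABELS, function(roi)
    at_index(observed$series[[roi]], predicted$series[[roi]]), numeric(1))
  structure(list(at_st = ats[["St"]], at_th = ats[["Th"]],
                 at_bfwb = ats[["BFWB"]],
                 at_total = at_total(ats[["St"]], ats[["Th"]], ats[["BFWB"]]),
                 n = observed$schedule$n_scans),
            class = "at_report")
}

#' @export
print.at_report <- function(x, ...) {
  cat(sprintf("AT agreement (N = %d): St %.4f  Th %.4f  BF+WB %.4f  total %.4f\n",
              x$n, x$at_st, x$at_th, x$at_bfwb, x$at_total))
  invisible(x)
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf("Measurement set '%s' (%s, %d scans)\n", x$patient_id,
              if (x$normalized) "normalized" else "raw count/pixel/s",
              x$schedule$n_scans))
  df <- data.frame(time_h = x$schedule$times_h, St = x$series$St,
                   Th = x$series$Th, BFWB = x$series$BFWB)
  if (!is.null(x$bkg)) df$BKG <- x$bkg
  print(df, row.names = FALSE)
  invisible(x)
}
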