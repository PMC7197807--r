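MEASUREMENT_COLUMNS <- c("patient_id", "time_h", "roi",
                         "value_counts_per_pixel_per_s")
KNOWN_ROIS <- c("St", "Th", "BFWB", "BKG", "Bl")

#' Read per-patient ROI measurements from CSV
#'
#' Expects columns `patient_id, time_h, roi, value_counts_per_pixel_per_s`,
#' one row per (patient, time, ROI). ROI labels are `St`, `Th`, `BFWB`,
#' optional `BKG` (consumed by background subtraction) and `Bl` (bladder;
#' read but dropped, it is not used in fitting). Each kept ROI of a patient
#' must cover the patient's full scan schedule.
#'
#' @param path CSV file path.
#' @return named list of raw [measurement_set()] objects, one per patient,
#'   in order of first appearance.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop_domain("measurement file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(MEASUREMENT_COLUMNS, names(df))
  if (length(missing_cols))
    stop_domain("measurement CSV is missing column(s): ",
                paste(missing_cols, collapse = ", "))
  if (!is.numeric(df$time_h) || anyNA(df$time_h))
    stop_domain("non-numeric or missing time_h values in ", path)
  if (!is.numeric(df$value_counts_per_pixel_per_s) ||
      anyNA(df$value_counts_per_pixel_per_s))
    stop_domain("non-numeric or missing measurement values in ", path)
  bad_roi <- !df$roi %in% KNOWN_ROIS
  if (any(bad_roi))
    stop_domain("unknown ROI label(s) at data line(s) ",
                paste(which(bad_roi), collapse = ", "), ": ",
                paste(unique(df$roi[bad_roi]), collapse = ", "))
  key <- paste(df$patient_id, df$time_h, df$roi)
  if (anyDuplicated(key))
    stop_domain("duplicate (patient, time, roi) row(s) at data line(s) ",
                paste(which(duplicated(key)), collapse = ", "))
  df <- df[df$roi != "Bl", ]

  out <- list()
  for (pid in unique(df$patient_id)) {
    d <- df[df$patient_id == pid, ]
    times <- sort(unique(d$time_h))
    sched <- scan_schedule(times)
    pick <- function(roi) {
      r <- d[d$roi == roi, ]
      if (roi == "BKG" && nrow(r) == 0L) return(NULL)
      if (nrow(r) != length(times) || !setequal(r$time_h, times))
        stop_domain("patient ", pid, ": ROI ", roi, " covers ", nrow(r),
                    " of ", length(times), " scan times (incomplete series)")
      r$value_counts_per_pixel_per_s[order(r$time_h)]
    }
    out[[as.character(pid)]] <- measurement_set(
      pid, sched, st = pick("St"), th = pick("Th"), bfwb = pick("BFWB"),
      bkg = pick("BKG"))
  }
  out
}

#' Write measurement sets (or a synthetic cohort) to CSV
#'
#' Inverse of [read_measurements()]; synthetic patients also get a truth
#' JSON (their generating parameters) next to the CSV when `truth_path`
#' is given.
#'
#' @param x a list of [measurement_set()] or `synthetic_patient` objects
#'   (or a single one).
#' @param path output CSV path.
#' @param truth_path optional path for the true-parameter JSON (written
#'   only when `x` carries synthetic patients).
#' @return `path`, invisibly.
#' @export
write_measurements <- function(x, path, truth_path = NULL) {
  if (inherits(x, "measurement_set") || inherits(x, "synthetic_patient"))
    x <- list(x)
  rows <- list(); truth <- list()
  for (item in x) {
    ms <- if (inherits(item, "synthetic_patient")) item$raw else item
    stopifnot(inherits(ms, "measurement_set"))
    if (inherits(item, "synthetic_patient"))
      truth[[as.character(ms$patient_id)]] <- list(
        half_lives = unclass(item$true_params$half_lives),
        branching = unclass(item$true_params$branching),
        gain = item$gain, background = item$background)
    series <- ms$series
    if (!is.null(ms$bkg)) series$BKG <- ms$bkg
    for (roi in names(series))
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = ms$patient_id, time_h = ms$schedule$times_h, roi = roi,
        value_counts_per_pixel_per_s = series[[roi]])
  }
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth_path) && length(truth))
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(path)
}

fit_result_row <- function(fr) {
  data.frame(patient_id = fr$patient_id,
             t_stomach_h = fr$theta[["t_stomach_h"]],
             t_bfwb_h = fr$theta[["t_bfwb_h"]],
             t_thyroid_h = fr$theta[["t_thyroid_h"]],
             i23 = fr$theta[["i23"]],
             at_st = fr$at_report$at_st, at_th = fr$at_report$at_th,
             at_bfwb = fr$at_report$at_bfwb,
             at_total = fr$at_report$at_total)
}

#' Write fit results and the cohort summary to a directory
#'
#' Emits one JSON per patient (estimate + AT report), `cohort.csv` with one
#' row per patient, and `summary.json` with the mean +/- SD of each free
#' parameter.
#'
#' @param results non-empty list of `fit_result` objects.
#' @param path output directory; created if absent.
#' @param summary optional precomputed [summarize_cohort()] result.
#' @return the directory path, invisibly.
#' @export
write_results <- function(results, path, summary = NULL) {
  if (!is.list(results) || length(results) < 1L ||
      !all(vapply(results, inherits, logical(1), "fit_result")))
    stop_domain("results must be a non-empty list of fit_result objects")
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  if (is.null(summary)) summary <- summarize_cohort(results)
  for (fr in results) {
    jsonlite::write_json(
      list(patient_id = fr$patient_id,
           estimate = list(half_lives = unclass(fr$estimate$half_lives),
                           branching = unclass(fr$estimate$branching),
                           physical_half_life_h =
                             fr$estimate$physical$half_life_h),
           at = list(at_st = fr$at_report$at_st, at_th = fr$at_report$at_th,
                     at_bfwb = fr$at_report$at_bfwb,
                     at_total = fr$at_report$at_total,
                     n = fr$at_report$n),
           objective = fr$objective, converged = fr$converged,
           n_evaluations = fr$n_evaluations),
      file.path(path, paste0("fit_", fr$patient_id, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  cohort <- do.call(rbind, lapply(results, fit_result_row))
  utils::write.csv(format(cohort, digits = 6, trim = TRUE),
                   file.path(path, "cohort.csv"),
                   row.names = FALSE, quote = FALSE)
  write_summary_json(summary, file.path(path, "summary.json"))
  invisible(path)
}

#' Read / write a cohort summary as JSON
#'
#' @param summary a [summarize_cohort()] result.
#' @param path JSON file path.
#' @return `write_summary_json()`: `path`, invisibly;
#'   `read_summary_json()`: a `cohort_summary` object.
#' @export
write_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "cohort_summary"))
  jsonlite::write_json(
    list(n_patients = summary$n_patients, mean = as.list(summary$mean),
         sd = as.list(summary$sd)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_summary_json
#' @export
read_summary_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = unlist(j$mean),
                 sd = unlist(lapply(j$sd, function(v) v %||% NA_real_)),
                 n_patients = j$n_patients),
            class = "cohort_summary")
}
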