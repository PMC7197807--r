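#' Configuration of the synthetic gamma-scan generator
#'
#' Emulates the statistical structure the analysis pipeline assumes: ROI
#' series sampled on the scan schedule from the compartment model, scaled
#' by an arbitrary per-patient detector gain, perturbed by multiplicative
#' Gaussian noise, and offset by a flat background that is also reported as
#' a BKG series (so background subtraction and normalization are exercised
#' end to end).
#'
#' @param n_patients number of patients to generate.
#' @param schedule a [scan_schedule()]; default the six clinical times.
#' @param source `"fixed"` draws the published nine-patient rows verbatim
#'   (cycling if `n_patients > 9` is an error in fixed mode); `"range"`
#'   draws each parameter uniformly from `ranges`.
#' @param ranges named list of `c(low, high)` for `t_stomach_h`, `t_bfwb_h`,
#'   `t_thyroid_h`, `i23`; defaults span the published cohort
#'   (0.30-1.30 h, 10-15 h, 35-50 h, 0.04-0.50).
#' @param noise_cov coefficient of variation of the multiplicative
#'   measurement noise (default 0.05).
#' @param gain_range per-patient detector gain drawn log-uniformly from
#'   this interval (default `[0.5, 5]`).
#' @param background_frac flat background level as a fraction of the
#'   patient's (gained, noise-free) first stomach signal (default 0.02).
#' @param seed master seed; per-patient substreams are derived from it so
#'   patient k's data do not depend on how many patients precede it.
#' @param physical a [physical_decay()] object.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 9L,
                             schedule = scan_schedule(),
                             source = c("fixed", "range"),
                             ranges = list(t_stomach_h = c(0.30, 1.30),
                                           t_bfwb_h    = c(10, 15),
                                           t_thyroid_h = c(35, 50),
                                           i23         = c(0.04, 0.50)),
                             noise_cov = 0.05,
                             gain_range = c(0.5, 5),
                             background_frac = 0.02,
                             seed = 1L,
                             physical = physical_decay()) {
  source <- match.arg(source)
  stopifnot(inherits(schedule, "scan_schedule"))
  if (!is.numeric(n_patients) || n_patients < 1)
    stop_domain("n_patients must be >= 1")
  if (noise_cov < 0) stop_domain("noise_cov must be >= 0")
  if (any(gain_range <= 0) || gain_range[1] > gain_range[2])
    stop_domain("gain_range must be positive with low <= high")
  if (background_frac < 0) stop_domain("background_frac must be >= 0")
  for (nm in theta_names) {
    b <- ranges[[nm]]
    if (is.null(b) || length(b) != 2L || anyNA(b) || b[1] > b[2])
      stop_domain("ranges$", nm, " must be c(low, high) with low <= high")
  }
  structure(list(n_patients = as.integer(n_patients), schedule = schedule,
                 source = source, ranges = ranges[theta_names],
                 noise_cov = noise_cov, gain_range = as.numeric(gain_range),
                 background_frac = background_frac, seed = as.integer(seed),
                 physical = physical),
            class = "generator_config")
}

# Deterministic per-patient substream: independent of patient order.
# Separate streams keep parameter draws uncorrelated with measurement noise.
patient_seed <- function(seed, draw_index, stream = 0L) {
  as.integer((as.double(seed) * 48271 + draw_index * 30011 +
                stream * 7919) %% 2147483629L)
}

#' Draw one patient's true parameters
#'
#' @param config a [generator_config()].
#' @param draw_index 1-based patient index; selects the published row in
#'   fixed mode and the random substream in range mode.
#' @return a [biokinetic_parameters()] object (always with
#'   `i25 = 1 - i23`, whole body tied to body fluid).
#' @export
sample_parameters <- function(config, draw_index) {
  stopifnot(inherits(config, "generator_config"))
  if (draw_index < 1) stop_domain("draw_index must be >= 1")
  if (config$source == "fixed") {
    tab <- cohort_parameter_table()
    if (draw_index > nrow(tab))
      stop_domain("fixed-source mode has only ", nrow(tab),
                  " parameter rows; draw_index = ", draw_index)
    return(patient_parameters(draw_index, config$physical))
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(patient_seed(config$seed, draw_index))
  th <- vapply(config$ranges, function(b) runif(1, b[1], b[2]), numeric(1))
  params_from_theta(th, list(i42 = 0.9, physical = config$physical))
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate one synthetic patient
#'
#' Solves the trajectory from `q0 = (1, 0, 0, 0, 0)`, projects the three
#' ROI series, applies `value <- gain * value * (1 + eps)` with
#' `eps ~ N(0, noise_cov)` truncated so values stay non-negative, then adds
#' a flat background to every ROI and emits a matching BKG series.
#'
#' @param params the patient's true [biokinetic_parameters()].
#' @param config a [generator_config()].
#' @param draw_index 1-based index selecting the noise substream.
#' @return object of class `synthetic_patient`: `true_params`, `raw`
#'   (a [measurement_set()] with BKG), `truth_trajectory`, `gain`,
#'   `background`.
#' @export
generate_patient <- function(params, config, draw_index = 1L) {
  stopifnot(inherits(params, "biokinetic_parameters"),
            inherits(config, "generator_config"))
  traj <- solve_trajectory(params, config$schedule$times_h)
  clean <- project_observables(traj, config$schedule,
                               patient_id = paste0("S", draw_index))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(patient_seed(config$seed, draw_index, stream = 1L))
  g <- exp(runif(1, log(config$gain_range[1]), log(config$gain_range[2])))
  noisy <- lapply(clean$series, function(v) {
    eps <- rnorm(length(v), 0, config$noise_cov)
    pmax(g * v * (1 + eps), 0)
  })
  bkg_level <- config$background_frac * g * clean$series$St[1]
  bkg <- rep(bkg_level, config$schedule$n_scans)
  raw <- measurement_set(clean$patient_id, config$schedule,
                         st = noisy$St + bkg_level,
                         th = noisy$Th + bkg_level,
                         bfwb = noisy$BFWB + bkg_level,
                         bkg = bkg)
  structure(list(true_params = params, raw = raw, truth_trajectory = traj,
                 gain = g, background = bkg_level),
            class = "synthetic_patient")
}

#' Generate a synthetic cohort
#'
#' @param config a [generator_config()].
#' @return list of [generate_patient()] results, one per patient,
#'   reproducible from `config$seed` and independent of generation order.
#' @examples
#' cohort <- generate_cohort(generator_config(n_patients = 3, noise_cov = 0))
#' cohort[[1]]$raw
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  lapply(seq_len(config$n_patients), function(i)
    generate_patient(sample_parameters(config, i), config, i))
}
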