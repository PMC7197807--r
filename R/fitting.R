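#' Configuration for per-patient parameter estimation
#'
#' Four parameters are free: the stomach half-life, one half-life shared by
#' body fluid and whole body, the thyroid half-life, and the body-fluid ->
#' thyroid branching ratio `i23` (with `i25 = 1 - i23`). The remaining
#' ratios are fixed (`i12 = i34 = 1`, `i42 = 0.9`, `i45 = 0.1`), matching
#' the structure of the published cohort table, which varies only these
#' four quantities across patients.
#'
#' @param bounds named list of `c(low, high)` bounds for `t_stomach_h`
#'   (default `[0.05, 5]` h), `t_bfwb_h` (`[1, 100]` h), `t_thyroid_h`
#'   (`[5, 500]` h) and `i23` (`[0, 1]`).
#' @param grid_resolution grid points per free parameter for the coarse
#'   search (>= 2); half-lives are gridded log-uniformly, `i23` uniformly.
#' @param i42 fixed whole-body -> body-fluid feedback fraction.
#' @param n_starts how many of the best grid points seed the local
#'   refinement.
#' @param n_random_starts extra random starts drawn inside the bounds from
#'   `seed`.
#' @param reltol relative convergence tolerance of the Nelder-Mead
#'   refinement.
#' @param max_iterations Nelder-Mead iteration cap per start.
#' @param seed integer seed making the random starts reproducible.
#' @param physical a [physical_decay()] object used for every candidate.
#' @return object of class `fit_config`.
#' @export
fit_config <- function(bounds = list(t_stomach_h = c(0.05, 5),
                                     t_bfwb_h    = c(1, 100),
                                     t_thyroid_h = c(5, 500),
                                     i23         = c(0, 1)),
                       grid_resolution = 6L,
                       i42 = 0.9,
                       n_starts = 3L,
                       n_random_starts = 2L,
                       reltol = 1e-12,
                       max_iterations = 2000L,
                       seed = 1L,
                       physical = physical_decay()) {
  need <- c("t_stomach_h", "t_bfwb_h", "t_thyroid_h", "i23")
  if (!all(need %in% names(bounds)))
    stop_domain("bounds must name all of: ", paste(need, collapse = ", "))
  for (nm in need) {
    b <- bounds[[nm]]
    if (!is.numeric(b) || length(b) != 2L || anyNA(b) || b[1] >= b[2])
      stop_domain("bounds for ", nm, " must be c(low, high) with low < high")
  }
  if (grid_resolution < 2) stop_domain("grid_resolution must be >= 2")
  check_fraction(i42, "i42")
  structure(list(bounds = bounds[need],
                 grid_resolution = as.integer(grid_resolution),
                 i42 = i42,
                 n_starts = as.integer(n_starts),
                 n_random_starts = as.integer(n_random_starts),
                 reltol = reltol,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed),
                 physical = physical),
            class = "fit_config")
}

theta_names <- c("t_stomach_h", "t_bfwb_h", "t_thyroid_h", "i23")

params_from_theta <- function(theta, config) {
  biokinetic_parameters(
    biological_half_lives(stomach_h = theta[[1]], bodyfluid_h = theta[[2]],
                          thyroid_h = theta[[3]]),
    branching_ratios(i23 = theta[[4]], i42 = config$i42),
    config$physical)
}

# Lean objective: AT_tot between normalized data and the normalized model
# projection, skipping all object construction on the hot path.
make_objective <- function(data, config) {
  times <- data$schedule$times_h
  obs <- data$series
  lp <- config$physical$lambda_p
  i42 <- config$i42
  q0 <- c(1, 0, 0, 0, 0)
  ln2 <- log(2)
  n_eval <- 0L
  f <- function(theta) {
    n_eval <<- n_eval + 1L
    l12 <- ln2 / theta[1]
    l2 <- ln2 / theta[2]
    l23 <- theta[4] * l2; l25 <- (1 - theta[4]) * l2
    l4 <- ln2 / theta[2]                 # whole body tied to body fluid
    l42 <- i42 * l4; l45 <- (1 - i42) * l4
    l34 <- ln2 / theta[3]
    A <- matrix(c(-l12, l12, 0, 0, 0,
                  0, -(l23 + l25), l23, 0, l25,
                  0, 0, -l34, l34, 0,
                  0, l42, 0, -(l42 + l45), l45,
                  0, 0, 0, 0, 0), 5, 5) - lp * diag(5)
    q <- propagate_expm_cpp(A, q0, times, 0)
    st <- q[1, ]; th <- q[3, ]; bfwb <- q[2, ] + q[4, ]
    ref <- st[1]
    if (!is.finite(ref) || ref <= 0) return(Inf)
    sqrt((mean((obs$St - st / ref)^2) + mean((obs$Th - th / ref)^2) +
          mean((obs$BFWB - bfwb / ref)^2)) / 3)
  }
  list(f = f, count = function() n_eval)
}

grid_axis <- function(bound, n, log_scale) {
  if (log_scale) exp(seq(log(bound[1]), log(bound[2]), length.out = n))
  else seq(bound[1], bound[2], length.out = n)
}

#' Estimate biokinetic parameters for one patient
#'
#' Minimizes the total AT between the normalized measured ROI series and
#' the normalized model projection over the four free parameters. A coarse
#' (log-)uniform grid over the configured bounds locates candidate basins;
#' the best grid points plus seeded random starts are refined by
#' Nelder-Mead on a bounded (logit) reparameterization. Deterministic given
#' the data and configuration (including its seed). Grid ties are broken
#' toward the smallest thyroid, then the smallest body-fluid half-life.
#'
#' @param data a [measurement_set()] with all three ROI series; raw data
#'   are background-subtracted and normalized first.
#' @param config a [fit_config()].
#' @return object of class `fit_result`: `patient_id`, `estimate`
#'   (a [biokinetic_parameters()]), `theta` (named free-parameter vector),
#'   `at_report`, `objective`, `converged`, `n_evaluations`.
#' @export
fit_patient <- function(data, config = fit_config()) {
  stopifnot(inherits(data, "measurement_set"))
  if (!all(ROI_LABELS %in% names(data$series)) ||
      any(vapply(data$series[ROI_LABELS], is.null, logical(1))))
    stop_domain("data must carry all three ROI series (St, Th, BFWB)")
  data <- normalize_dataset(data)
  obj <- make_objective(data, config)
  b <- config$bounds
  lo <- vapply(b, `[`, numeric(1), 1L)
  hi <- vapply(b, `[`, numeric(1), 2L)
  log_scale <- c(TRUE, TRUE, TRUE, FALSE)

  # coarse grid
  axes <- lapply(seq_along(b), function(i)
    grid_axis(b[[i]], config$grid_resolution, log_scale[i]))
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- theta_names
  vals <- apply(grid, 1L, obj$f)
  if (!any(is.finite(vals)))
    stop_domain("fit failure: objective non-finite everywhere on the grid")
  ord <- order(vals, grid[, "t_thyroid_h"], grid[, "t_bfwb_h"])
  starts <- grid[ord[seq_len(min(config$n_starts, nrow(grid)))], ,
                 drop = FALSE]
  if (config$n_random_starts > 0) {
    rng <- local({
      set.seed(config$seed)
      matrix(runif(4L * config$n_random_starts), ncol = 4L, byrow = TRUE)
    })
    rand <- t(apply(rng, 1L, function(u) {
      th <- ifelse(log_scale, exp(log(lo) + u * (log(hi) - log(lo))),
                   lo + u * (hi - lo))
      th
    }))
    colnames(rand) <- theta_names
    starts <- rbind(starts, rand)
  }

  # bounded logit reparameterization keeps Nelder-Mead inside the box
  eps <- 1e-9
  to_z <- function(theta) {
    fr <- pmin(pmax((theta - lo) / (hi - lo), eps), 1 - eps)
    qlogis(fr)
  }
  to_theta <- function(z) lo + plogis(z) * (hi - lo)
  obj_z <- function(z) obj$f(to_theta(z))

  best_theta <- grid[ord[1L], ]
  best_val <- vals[ord[1L]]
  converged <- FALSE
  for (k in seq_len(nrow(starts))) {
    res <- stats::optim(to_z(starts[k, ]), obj_z, method = "Nelder-Mead",
                        control = list(reltol = config$reltol,
                                       maxit = config$max_iterations))
    if (res$value < best_val) {
      best_val <- res$value
      best_theta <- to_theta(res$par)
      converged <- res$convergence == 0L
    }
  }
  names(best_theta) <- theta_names

  estimate <- params_from_theta(best_theta, config)
  predicted <- project_observables(
    solve_trajectory(estimate, data$schedule$times_h),
    data$schedule, patient_id = data$patient_id)
  report <- at_report(data, predicted)
  structure(list(patient_id = data$patient_id,
                 estimate = estimate,
                 theta = best_theta,
                 at_report = report,
                 objective = report$at_total,
                 converged = converged,
                 n_evaluations = obj$count()),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit for patient '%s' (%d objective evaluations%s)\n",
              x$patient_id, x$n_evaluations,
              if (x$converged) "" else ", refinement not converged"))
  cat(sprintf("  t_stomach %.2f h  t_bfwb %.2f h  t_thyroid %.2f h  i23 %.2f\n",
              x$theta[1], x$theta[2], x$theta[3], x$theta[4]))
  print(x$at_report)
  invisible(x)
}

extract_theta <- function(x) {
  if (inherits(x, "fit_result")) return(x$theta)
  if (inherits(x, "biokinetic_parameters"))
    return(c(t_stomach_h = x$half_lives$stomach_h,
             t_bfwb_h = x$half_lives$bodyfluid_h,
             t_thyroid_h = x$half_lives$thyroid_h,
             i23 = x$branching$i23))
  if (is.numeric(x) && length(x) >= 4L) return(x[1:4])
  stop_domain("cannot extract parameters from object of class ",
              paste(class(x), collapse = "/"))
}

#' Cohort summary: mean and sample SD of each fitted parameter
#'
#' @param results list of `fit_result` or [biokinetic_parameters()]
#'   objects, or a data.frame with columns `t_stomach_h`, `t_bfwb_h`,
#'   `t_thyroid_h`, `i23` (e.g. [cohort_parameter_table()]).
#' @return object of class `cohort_summary`: per-parameter `mean` and
#'   sample `sd` (n - 1 denominator; `NA` when fewer than two patients)
#'   for the four free parameters and the derived `i25`, plus `n_patients`.
#' @examples
#' summarize_cohort(cohort_parameter_table())
#' @export
summarize_cohort <- function(results) {
  if (is.data.frame(results)) {
    need <- theta_names
    if (!all(need %in% names(results)))
      stop_domain("data.frame must have columns ",
                  paste(need, collapse = ", "))
    mat <- as.matrix(results[, need])
  } else {
    if (!is.list(results) || length(results) < 1L)
      stop_domain("results must be a non-empty list or data.frame")
    mat <- t(vapply(results, extract_theta, numeric(4)))
    colnames(mat) <- theta_names
  }
  if (nrow(mat) < 1L) stop_domain("cohort is empty")
  mat <- cbind(mat, i25 = 1 - mat[, "i23"])
  n <- nrow(mat)
  structure(list(mean = colMeans(mat),
                 sd = if (n >= 2L) apply(mat, 2L, sd)
                      else setNames(rep(NA_real_, ncol(mat)), colnames(mat)),
                 n_patients = n),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary (n = %d patients), mean +/- sample SD\n",
              x$n_patients))
  lab <- c(t_stomach_h = "stomach T1/2 [h]", t_bfwb_h = "BF&WB T1/2 [h]",
           t_thyroid_h = "thyroid T1/2 [h]", i23 = "i23", i25 = "i25")
  for (nm in names(lab))
    cat(sprintf("  %-17s %6.2f +/- %s\n", lab[[nm]], x$mean[[nm]],
                if (is.na(x$sd[[nm]])) "NA" else sprintf("%.2f", x$sd[[nm]])))
  invisible(x)
}
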