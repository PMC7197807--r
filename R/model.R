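#' Generator matrix of the five-compartment kinetic system
#'
#' Builds the 5x5 matrix A such that `dq/dt = A q` for the compartment
#' activity vector q = (stomach, body fluid, thyroid, whole body,
#' excretion). The biological part B (A = B - lambda_P * I) moves activity
#' between compartments without loss, so its column sums are zero; physical
#' decay removes activity from every compartment at the same rate.
#'
#' Activity enters the body fluid from the stomach, is taken up by the
#' thyroid or excreted, passes from thyroid to whole body, and from the
#' whole body either feeds back to the body fluid or is excreted; the
#' excretion compartment closes the balance.
#'
#' @param params a [biokinetic_parameters()] object.
#' @return 5x5 numeric matrix with dimnames
#'   `stomach, bodyfluid, thyroid, wholebody, excretion`.
#' @export
build_rate_matrix <- function(params) {
  r <- transfer_rates(params)
  lp <- params$physical$lambda_p
  A <- matrix(0, 5, 5, dimnames = list(compartment_names, compartment_names))
  A[1, 1] <- -r[["lambda12"]]
  A[2, 1] <-  r[["lambda12"]]
  A[2, 2] <- -(r[["lambda23"]] + r[["lambda25"]])
  A[3, 2] <-  r[["lambda23"]]
  A[5, 2] <-  r[["lambda25"]]
  A[3, 3] <- -r[["lambda34"]]
  A[4, 3] <-  r[["lambda34"]]
  A[2, 4] <-  r[["lambda42"]]
  A[5, 4] <-  r[["lambda45"]]
  A[4, 4] <- -(r[["lambda42"]] + r[["lambda45"]])
  A - lp * diag(5)
}

check_times <- function(times_h) {
  if (!is.numeric(times_h) || length(times_h) < 1L || anyNA(times_h) ||
      any(times_h < 0))
    stop_domain("times_h must be non-negative numbers")
  if (is.unsorted(times_h, strictly = FALSE))
    stop_domain("times_h must be sorted ascending")
  as.numeric(times_h)
}

check_q0 <- function(q0) {
  if (!is.numeric(q0) || length(q0) != 5L || anyNA(q0) || any(q0 < 0))
    stop_domain("q0 must be a non-negative numeric vector of length 5")
  as.numeric(q0)
}

new_trajectory <- function(times_h, qmat, params) {
  dimnames(qmat) <- list(NULL, compartment_names)
  structure(list(times_h = times_h, q = qmat, params = params),
            class = "trajectory")
}

#' Solve the compartment system exactly (matrix exponential)
#'
#' Closed-form solution of the constant-coefficient linear system
#' `dq/dt = A q` by scaling-and-squaring matrix exponential, propagated
#' between consecutive requested times. Correct also when eigenvalues
#' coincide (body fluid and whole body sharing a half-life), where a
#' spectral decomposition would break down.
#'
#' @param params a [biokinetic_parameters()] object.
#' @param times_h sorted non-negative sampling times, hours.
#' @param q0 initial activity fractions, default `c(1, 0, 0, 0, 0)`: the
#'   whole administered capsule dissolves instantly in the stomach and the
#'   administered activity is normalized to 1.
#' @return object of class `trajectory`: list with `times_h` and `q`, an
#'   `length(times_h) x 5` matrix of activity fractions.
#' @examples
#' tr <- solve_trajectory(patient_parameters(1), c(1, 4, 24, 48, 72, 168))
#' rowSums(tr$q)   # = exp(-lambda_P t): activity only leaves by decay
#' @export
solve_trajectory <- function(params, times_h, q0 = c(1, 0, 0, 0, 0)) {
  stopifnot(inherits(params, "biokinetic_parameters"))
  times_h <- check_times(times_h)
  q0 <- check_q0(q0)
  A <- build_rate_matrix(params)
  qmat <- t(propagate_expm_cpp(A, q0, times_h, 0))
  new_trajectory(times_h, qmat, params)
}

#' Independent RK4 oracle for the compartment system
#'
#' Classical fixed-step fourth-order Runge-Kutta integration of the same
#' system, used to cross-check [solve_trajectory()]. Converges to the exact
#' solution at O(step^4).
#'
#' @inheritParams solve_trajectory
#' @param step_h integration step, hours; must be positive and no larger
#'   than the smallest gap between consecutive sampling times.
#' @return a `trajectory` object.
#' @export
solve_trajectory_rk4 <- function(params, times_h, q0 = c(1, 0, 0, 0, 0),
                                 step_h = 0.001) {
  stopifnot(inherits(params, "biokinetic_parameters"))
  times_h <- check_times(times_h)
  q0 <- check_q0(q0)
  check_positive_finite(step_h, "step_h")
  gaps <- diff(c(0, times_h))
  min_gap <- min(gaps[gaps > 0])
  if (step_h > min_gap + 1e-12)
    stop_domain("step_h (", step_h, ") exceeds the smallest spacing ",
                "between sampling times (", min_gap, ")")
  A <- build_rate_matrix(params)
  qmat <- t(rk4_cpp(A, q0, times_h, step_h))
  new_trajectory(times_h, qmat, params)
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Compartment trajectory (", length(x$times_h), " time points)\n",
      sep = "")
  print(cbind(time_h = x$times_h, round(x$q, 6)))
  invisible(x)
}
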