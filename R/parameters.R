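#' @useDynLib i131biokin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd setNames optim qlogis plogis median
#' @importFrom utils read.csv write.csv
NULL

#' Default physical half-life of I-131 in hours (8.02 days)
#'
#' The kinetic model applies one physical decay constant to every
#' compartment; this constant is the package default and can be overridden
#' in [physical_decay()] or any configuration file.
#' @export
I131_HALF_LIFE_H <- 192.5

compartment_names <- c("stomach", "bodyfluid", "thyroid", "wholebody",
                       "excretion")

stop_domain <- function(...) stop(..., call. = FALSE)

check_positive_finite <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_domain(what, " must be a single finite value > 0, got ",
                deparse(substitute(x)), " = ", format(x))
  invisible(x)
}

check_fraction <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop_domain(what, " must be a fraction in [0, 1], got ", format(x))
  invisible(x)
}

#' Physical decay of a radionuclide
#'
#' @param half_life_h physical half-life in hours; defaults to I-131
#'   ([I131_HALF_LIFE_H]).
#' @return object of class `physical_decay` with fields `half_life_h` and
#'   `lambda_p` (decay constant, h^-1, equal to `log(2) / half_life_h`).
#' @examples
#' physical_decay()$lambda_p       # I-131: 0.0036 h^-1
#' @export
physical_decay <- function(half_life_h = I131_HALF_LIFE_H) {
  check_positive_finite(half_life_h, "physical half-life")
  structure(list(half_life_h = half_life_h,
                 lambda_p = log(2) / half_life_h),
            class = "physical_decay")
}

#' Branching ratios of the five-compartment iodine model
#'
#' Fractions routing the biological outflow of each compartment:
#' stomach -> body fluid (`i12`), body fluid -> thyroid (`i23`) or
#' excretion (`i25`), thyroid -> whole body (`i34`), whole body -> body
#' fluid (`i42`) or excretion (`i45`). Outflow fractions of a compartment
#' must sum to one; the stomach and thyroid each have a single exit
#' (`i12 = i34 = 1`).
#'
#' @param i23 body fluid -> thyroid fraction.
#' @param i25 body fluid -> excretion fraction, default `1 - i23`.
#' @param i12,i34 single-exit fractions, fixed at 1.
#' @param i42 whole body -> body fluid (feedback) fraction, default 0.9.
#' @param i45 whole body -> excretion fraction, default `1 - i42`.
#' @return object of class `branching_ratios`.
#' @export
branching_ratios <- function(i23, i25 = 1 - i23, i12 = 1, i34 = 1,
                             i42 = 0.9, i45 = 1 - i42) {
  for (nm in c("i12", "i23", "i25", "i34", "i42", "i45"))
    check_fraction(get(nm), nm)
  tol <- 1e-9
  if (abs(i23 + i25 - 1) > tol)
    stop_domain("i23 + i25 must equal 1 (body-fluid outflow splits ",
                "completely); got ", i23 + i25)
  if (abs(i42 + i45 - 1) > tol)
    stop_domain("i42 + i45 must equal 1 (whole-body outflow splits ",
                "completely); got ", i42 + i45)
  structure(list(i12 = unname(i12), i23 = unname(i23), i25 = unname(i25),
                 i34 = unname(i34), i42 = unname(i42), i45 = unname(i45)),
            class = "branching_ratios")
}

#' Biological half-lives of the four kinetic compartments
#'
#' @param stomach_h,bodyfluid_h,thyroid_h,wholebody_h biological half-lives
#'   in hours (all > 0). `wholebody_h` defaults to `bodyfluid_h`, the tying
#'   used for the patient fits (the cohort table reports one shared
#'   "BF&WB" value).
#' @return object of class `biological_half_lives`.
#' @export
biological_half_lives <- function(stomach_h, bodyfluid_h, thyroid_h,
                                  wholebody_h = bodyfluid_h) {
  check_positive_finite(stomach_h, "stomach half-life")
  check_positive_finite(bodyfluid_h, "body-fluid half-life")
  check_positive_finite(thyroid_h, "thyroid half-life")
  check_positive_finite(wholebody_h, "whole-body half-life")
  structure(list(stomach_h = unname(stomach_h),
                 bodyfluid_h = unname(bodyfluid_h),
                 thyroid_h = unname(thyroid_h),
                 wholebody_h = unname(wholebody_h)),
            class = "biological_half_lives")
}

#' Full parameter set of the five-compartment biokinetic model
#'
#' @param half_lives a [biological_half_lives()] object.
#' @param branching a [branching_ratios()] object.
#' @param physical a [physical_decay()] object; default I-131.
#' @return object of class `biokinetic_parameters`.
#' @seealso [transfer_rates()], [build_rate_matrix()]
#' @export
biokinetic_parameters <- function(half_lives, branching,
                                  physical = physical_decay()) {
  stopifnot(inherits(half_lives, "biological_half_lives"),
            inherits(branching, "branching_ratios"),
            inherits(physical, "physical_decay"))
  structure(list(half_lives = half_lives, branching = branching,
                 physical = physical),
            class = "biokinetic_parameters")
}

#' Biological transfer rate from one compartment
#'
#' First-order rate `lambda_ij = i_ij * log(2) / T_i(bio)`: the fraction
#' `i_ij` of compartment i's biological clearance (half-life `half_life_h`)
#' routed to compartment j.
#'
#' @param half_life_h biological half-life of the source compartment, hours.
#' @param branching fraction of the outflow routed to the destination.
#' @return rate in h^-1.
#' @examples
#' decay_constant(0.696, 1.0)   # stomach emptying, reference adult
#' @export
decay_constant <- function(half_life_h, branching) {
  check_positive_finite(half_life_h, "biological half-life")
  check_fraction(branching, "branching ratio")
  unname(branching * log(2) / half_life_h)
}

#' All six transfer rates of a parameter set
#'
#' @param params a [biokinetic_parameters()] object.
#' @return named vector (h^-1): `lambda12`, `lambda23`, `lambda25`,
#'   `lambda34`, `lambda42`, `lambda45`.
#' @export
transfer_rates <- function(params) {
  stopifnot(inherits(params, "biokinetic_parameters"))
  hl <- params$half_lives; br <- params$branching
  c(lambda12 = decay_constant(hl$stomach_h,   br$i12),
    lambda23 = decay_constant(hl$bodyfluid_h, br$i23),
    lambda25 = decay_constant(hl$bodyfluid_h, br$i25),
    lambda34 = decay_constant(hl$thyroid_h,   br$i34),
    lambda42 = decay_constant(hl$wholebody_h, br$i42),
    lambda45 = decay_constant(hl$wholebody_h, br$i45))
}

#' Effective half-life combining physical decay and biological clearance
#'
#' `1/T_eff = 1/T_phys + 1/T_bio`, the harmonic combination governing the
#' net disappearance of activity from a compartment.
#'
#' @param physical_h physical half-life, hours.
#' @param biological_h biological half-life, hours.
#' @return effective half-life, hours.
#' @examples
#' effective_half_life(192, 450)   # ~135 h for iodine held in the thyroid
#' @export
effective_half_life <- function(physical_h, biological_h) {
  check_positive_finite(physical_h, "physical half-life")
  check_positive_finite(biological_h, "biological half-life")
  1 / (1 / physical_h + 1 / biological_h)
}

#' Published per-patient parameter table of the nine-patient cohort
#'
#' Biological half-lives (hours) and branching ratios fitted for nine
#' thyroid-remnant ablation patients. Body fluid and whole body share one
#' half-life. `i12 = i34 = 1`, `i42 = 0.9`, `i45 = 0.1` for every row.
#'
#' @return data.frame with columns `patient_id`, `t_stomach_h`, `t_bfwb_h`,
#'   `t_thyroid_h`, `i23`, `i25`.
#' @export
cohort_parameter_table <- function() {
  i23 <- c(0.18, 0.50, 0.30, 0.15, 0.04, 0.30, 0.18, 0.15, 0.08)
  data.frame(
    patient_id  = paste0("P", 1:9),
    t_stomach_h = c(0.50, 0.30, 0.30, 0.33, 0.35, 0.60, 0.45, 0.70, 1.30),
    t_bfwb_h    = c(15, 14, 10, 11, 12, 15, 13, 12.5, 11),
    t_thyroid_h = c(35, 50, 40, 40, 50, 40, 45, 40, 45),
    i23 = i23,
    i25 = 1 - i23,
    stringsAsFactors = FALSE
  )
}

#' Reference healthy-adult parameters (Eckerman)
#'
#' The ICRP-style reference values for a healthy adult male: stomach
#' 0.696 h, body fluid 6 h, thyroid 1920 h, whole body 288 h, with
#' `i23 = 0.3`, `i42 = 0.9`. Unlike the patient rows, body fluid and whole
#' body have distinct half-lives.
#'
#' @param physical a [physical_decay()] object; default I-131.
#' @return a [biokinetic_parameters()] object.
#' @export
reference_adult_parameters <- function(physical = physical_decay()) {
  biokinetic_parameters(
    biological_half_lives(stomach_h = 0.696, bodyfluid_h = 6,
                          thyroid_h = 1920, wholebody_h = 288),
    branching_ratios(i23 = 0.30),
    physical
  )
}

#' Parameters from one cohort-table row (or the cohort average)
#'
#' @param index row of [cohort_parameter_table()] (1-9), or `"average"` for
#'   the cohort mean row (0.54 / 12.6 / 42.8 h, `i23 = 0.21`).
#' @param physical a [physical_decay()] object; default I-131.
#' @return a [biokinetic_parameters()] object with
#'   `wholebody_h = bodyfluid_h`.
#' @export
patient_parameters <- function(index, physical = physical_decay()) {
  if (identical(index, "average"))
    return(biokinetic_parameters(
      biological_half_lives(0.54, 12.6, 42.8),
      branching_ratios(i23 = 0.21), physical))
  tab <- cohort_parameter_table()
  if (!is.numeric(index) || length(index) != 1L || is.na(index) ||
      index < 1 || index > nrow(tab))
    stop_domain("patient index must be 1..", nrow(tab), " or \"average\"")
  row <- tab[as.integer(index), ]
  biokinetic_parameters(
    biological_half_lives(row$t_stomach_h, row$t_bfwb_h, row$t_thyroid_h),
    branching_ratios(i23 = row$i23), physical)
}

#' Read / write model parameters as JSON
#'
#' The JSON layout has keys `half_lives` (`stomach_h`, `bodyfluid_h`,
#' `thyroid_h`, `wholebody_h`), `branching` (`i12` .. `i45`) and
#' `physical_half_life_h`. Missing fields fall back to the cohort-average
#' defaults.
#'
#' @param path file path.
#' @return `read_parameters_json()`: a [biokinetic_parameters()] object;
#'   `write_parameters_json()`: `path`, invisibly.
#' @export
read_parameters_json <- function(path) {
  if (!file.exists(path)) stop_domain("parameter file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- patient_parameters("average")
  hl <- utils::modifyList(defaults$half_lives, as.list(j$half_lives %||% list()))
  br <- utils::modifyList(defaults$branching, as.list(j$branching %||% list()))
  biokinetic_parameters(
    biological_half_lives(hl$stomach_h, hl$bodyfluid_h, hl$thyroid_h,
                          hl$wholebody_h),
    branching_ratios(i23 = br$i23, i25 = br$i25, i12 = br$i12, i34 = br$i34,
                     i42 = br$i42, i45 = br$i45),
    physical_decay(j$physical_half_life_h %||% I131_HALF_LIFE_H))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_parameters_json
#' @param params a [biokinetic_parameters()] object.
#' @export
write_parameters_json <- function(params, path) {
  stopifnot(inherits(params, "biokinetic_parameters"))
  jsonlite::write_json(
    list(half_lives = unclass(params$half_lives),
         branching = unclass(params$branching),
         physical_half_life_h = params$physical$half_life_h),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.biokinetic_parameters <- function(x, ...) {
  hl <- x$half_lives; br <- x$branching
  cat("Five-compartment biokinetic parameters\n")
  cat(sprintf("  biological half-lives [h]: stomach %.3g, body fluid %.3g, thyroid %.3g, whole body %.3g\n",
              hl$stomach_h, hl$bodyfluid_h, hl$thyroid_h, hl$wholebody_h))
  cat(sprintf("  branching: i12 %.2f  i23 %.2f  i25 %.2f  i34 %.2f  i42 %.2f  i45 %.2f\n",
              br$i12, br$i23, br$i25, br$i34, br$i42, br$i45))
  cat(sprintf("  physical half-life: %.4g h (lambda_P = %.4g h^-1)\n",
              x$physical$half_life_h, x$physical$lambda_p))
  invisible(x)
}
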