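---
title: "A five-compartment biokinetic model of I-131: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A five-compartment biokinetic model of I-131: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(i131biokin)
```

## The model

Orally administered I-131 is tracked through five compartments: stomach
(q1), body fluid (q2), thyroid (q3), whole body (q4) and excretion (q5).
Transfers are first order, so the state obeys a constant-coefficient linear
system `dq/dt = A q`. Each biological rate is

```
lambda_ij = i_ij * ln(2) / T_i(bio)
```

with `i_ij` the fraction of compartment i's outflow routed to j and
`T_i(bio)` the biological half-life of i. The routing is: stomach -> body
fluid (i12 = 1); body fluid -> thyroid (i23) or excretion (i25 = 1 - i23);
thyroid -> whole body (i34 = 1); whole body -> body fluid (i42 = 0.9,
a metabolic feedback path) or excretion (i45 = 0.1). Physical decay
(`lambda_P = ln 2 / T_phys`) acts identically on every compartment, so
`A = B - lambda_P * I` where the biological part B has zero column sums.
That structure yields the conservation law used throughout the tests:

```
sum_k q_k(t) = exp(-lambda_P * t) * sum_k q_k(0)
```

Two modelling choices deserve mention:

* **The excretion compartment closes the system.** The four kinetic
  equations for q1..q4 do not track voided activity; we add
  `dq5/dt = lambda25 q2 + lambda45 q4 - lambda_P q5` so that the balance
  above is exact and testable. Physical decay is applied inside the
  excretion compartment too — activity decays wherever it resides; this
  choice is unobservable in the scan ROIs but keeps the invariant clean.
* **Initial condition.** The capsule dissolves essentially instantly in the
  stomach, so `q(0) = (1, 0, 0, 0, 0)` with administered activity
  normalized to 1.

The physical half-life of I-131 defaults to 192.5 h (8.02 d) and is
configurable everywhere; the classic worked example
`effective_half_life(192, 450) = 134.58 ~ 135 h` uses 192 h because that is
the figure in the source calculation.

The abstract of the source study lists the whole-body split as
i42 = 0.1 / i45 = 0.9, while its parameter table and the reference-adult
values both give i42 = 0.9 / i45 = 0.1. We adopt the table's 0.9/0.1; the
feedback-dominated split is also what produces the observed slow late-time
washout.

## Solvers

`solve_trajectory()` evaluates the exact solution
`q(t) = expm(A (t - t0)) q(t0)`, propagated between consecutive requested
times, using a scaling-and-squaring Padé matrix exponential (Armadillo's
`expmat`). A spectral decomposition would be the textbook alternative, but
it degenerates when eigenvalues coincide — which is not a corner case here:
every patient fit ties the body-fluid and whole-body half-lives, giving
repeated diagonal rates. Scaling-and-squaring has no such failure mode.

`solve_trajectory_rk4()` is an independent classical fixed-step
Runge-Kutta-4 integrator over the same system, used as an oracle: at step
0.001 h the two solutions agree to better than 1e-6 on the six scan times
for all nine patient parameter rows (they actually agree to ~1e-13), and a
convergence test confirms the expected fourth-order error reduction (~16x
per step halving). The step must not exceed the smallest gap between
requested times; the final partial step covers any remainder so sampling
lands exactly on each time.

## Observation model and the AT index

The scans yield three ROI series per patient: St (stomach), Th (thyroid)
and BFWB (body fluid + whole body = q2 + q4). Excreted activity (and the
bladder ROI sometimes drawn on the images) is excluded — it is not used in
the fits. Raw rates in count/pixel/s are background-corrected by
subtracting the BKG ROI, clamping negative net rates to zero with a warning
(the convention for over-subtracted backgrounds; negative activity is
unphysical). Each patient's dataset is then normalized by the stomach value
at the first scan (1 h, the maximal stomach reading), which becomes the
dimensionless standard 1.0.

Agreement between a normalized observed series Y_obs and model prediction
Y_pred is measured by

```
AT = sqrt( sum_i (Y_obs_i - Y_pred_i)^2 / N ),   N = number of scans (6)
AT_tot = sqrt( (AT_St^2 + AT_Th^2 + AT_BFWB^2) / 3 )
```

The printed formulae in the source omit the radical, but the statistic is
described as an extension of the conventional RMS ("mean square root"), and
only the rooted form has the same units and scale as the normalized
intensities; we therefore use the RMS convention for both AT and AT_tot.
Model predictions are made commensurate with the data by normalizing them
the same way — dividing by the predicted stomach value at the first scan —
which makes AT invariant to any detector gain.

## Parameter estimation

Exactly four parameters are free: `t_stomach_h`, one `t_bfwb_h` shared by
body fluid and whole body, `t_thyroid_h`, and `i23` (with `i25 = 1 - i23`).
The published cohort table varies only these across patients while
`i12 = i34 = 1`, `i42 = 0.9`, `i45 = 0.1` are constant, so we fix the
constants and tie the two systemic half-lives; freeing them on six scan
times per ROI would be poorly identifiable anyway.

The source describes its optimizer only as iterative inversion, which does
not identify an algorithm; we specify a reproducible one:

1. **Coarse grid** over the bounds (`t_stomach` 0.05–5 h, `t_bfwb`
   1–100 h, `t_thyroid` 5–500 h, `i23` 0–1; defaults 6 points per axis,
   log-spaced for half-lives). Ties are broken toward the smallest thyroid,
   then smallest body-fluid half-life.
2. **Nelder-Mead refinement** from the best grid points (default 3) plus a
   few seeded random starts (default 2), on a logit reparameterization of
   the box so iterates cannot leave the bounds. Relative tolerance 1e-12,
   at most 2000 iterations per start.

The result is deterministic given the data and the configuration seed, and
the refined objective can never exceed the best grid value. On noise-free
synthetic data the true parameters are recovered to well under 1 % with
AT_tot below 1e-3 (tested for all nine published rows).

Cohort summaries report the arithmetic mean and the sample SD (n - 1
denominator) of each free parameter; with a single patient the SD is
reported as missing. Reported values are rounded to two decimals
(half-lives and fractions), the precision of the published table.

## The synthetic-data generator

No per-scan clinical intensities were published, so the generator is the
package's stand-in for the gamma camera. It emulates exactly the structure
the pipeline assumes:

* the six-scan schedule at 1, 4, 24, 48, 72, 168 h;
* true parameters either taken verbatim from the nine published patient
  rows or drawn uniformly from ranges spanning them (stomach 0.30–1.30 h,
  BF&WB 10–15 h, thyroid 35–50 h, i23 0.04–0.50);
* a per-patient detector gain, log-uniform on [0.5, 5] — arbitrary, since
  normalization must cancel it;
* multiplicative Gaussian noise `value * (1 + eps)`,
  `eps ~ N(0, CoV)`, truncated at zero, with CoV = 0.05 by default. The
  source quotes only the capsule-activity batch variation (< 1 %); per-scan
  ROI uncertainty is unpublished, and 5 % is a realistic planar-scan ROI
  repeatability figure. It is a stand-in, and flagged as such;
* a flat background at 2 % of the (gained) first stomach signal, emitted
  both inside every ROI series and as a BKG series, so background
  subtraction and normalization are exercised end to end.

Gaussian multiplicative noise was chosen over Poisson counting noise
because the data are rates per pixel without the total-count information
Poisson scaling would need. Seeding uses one master seed with deterministic
per-patient substreams (separate streams for parameter draws and
measurement noise), so a patient's data do not depend on cohort size or
order.

**What a green test establishes — and what it does not.** The generator
shares its forward model with the fitter, so recovery tests validate the
inverse machinery (identifiability on this schedule, normalization,
background handling, optimizer correctness), not the biological fidelity of
the five-compartment structure. Real scans add ROI-delineation error,
attenuation and scatter, organ overlap, and model misspecification that the
generator deliberately omits. Consequently the published per-patient AT
values (means 0.056 / 0.017 / 0.044, total 0.045) cannot be reproduced
here; the tests assert instead the properties that must hold: near-zero AT
and exact parameter recovery without noise, and median recovery errors
under 20 % per half-life (|error| < 0.10 for i23) at 5 % noise over 50
seeded replicates.

## Numerical and degenerate-input conventions

* Hours everywhere; rates in 1/h.
* Conservation is asserted to 1e-8, solver cross-agreement to 1e-6,
  AT identities to 1e-12.
* A dataset whose first stomach reading is zero cannot be normalized and is
  rejected as unusable (this is also how an all-zero series fails).
* Negative net count rates clamp to zero with a warning rather than erroring:
  a marginally over-subtracted background should not kill a batch run.
* Objective values that are non-finite over the whole grid abort the fit
  with an explicit failure.

## Limitations

* The two systemic half-lives are tied; cohorts where body fluid and whole
  body genuinely differ need a different configuration (the reference-adult
  parameter set, with 6 h vs 288 h, can be represented but not fitted).
* No uncertainty is quantified per patient (no bootstrap or information
  matrix); only the cross-patient SD is reported.
* Six time points constrain four parameters: the stomach half-life is
  informed almost entirely by the 1 h and 4 h scans and is the least
  precisely recovered under noise.
* The generator does not simulate images, ROI geometry, attenuation or
  scatter; bladder activity is not modelled as an ROI.
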