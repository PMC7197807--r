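# i131biokin

Compartmental biokinetic modelling of orally administered radioiodine
(I-131) in thyroid-remnant ablation patients, built around serial planar
gamma-camera scans.

After thyroidectomy, patients receive an I-131 capsule (~1110 MBq) to ablate
residual thyroid tissue and are scanned repeatedly over the following week.
The activity seen in the scan regions of interest (ROIs) — stomach, thyroid,
and body fluid + whole body — is the observable trace of a five-compartment
first-order kinetic system. This package implements that system end to end
for physicists and modellers in nuclear medicine:

* **Forward kinetics.** Compartments q₁ (stomach), q₂ (body fluid),
  q₃ (thyroid), q₄ (whole body), q₅ (excretion) obey `dq/dt = A q`, where
  each biological transfer rate is `λᵢⱼ = iᵢⱼ · ln2 / Tᵢ(bio)` (branching
  ratio × biological half-life) and every compartment additionally decays
  with the physical constant `λ_P = ln2 / 192.5 h`. The system is solved
  exactly by matrix exponential and cross-checked by an independent
  fixed-step RK4 integrator.
* **Observation model.** ROI projection (St = q₁, Th = q₃, BF+WB = q₂ + q₄;
  excreted activity is out of view), background subtraction, and
  normalization of every series to the first stomach reading (set to 1.0),
  which cancels the detector gain.
* **Agreement statistic.** The AT index between normalized observed and
  predicted series, `AT = √(Σᵢ (Y_obs,i − Y_pred,i)² / N)` with N = 6 scans,
  and `AT_tot = √((AT_St² + AT_Th² + AT_BFWB²)/3)`; 0 means perfect
  agreement.
* **Inverse problem.** Per-patient estimation of the four free parameters
  (stomach half-life, a half-life shared by body fluid and whole body,
  thyroid half-life, and the uptake fraction i23) by minimizing AT_tot:
  coarse log-uniform grid search plus seeded Nelder-Mead refinement within
  bounds. Cohorts are summarized as mean ± sample SD.
* **Synthetic scans.** A generator producing gamma-scan-like datasets
  (model trajectory × per-patient gain × multiplicative Gaussian noise +
  flat background, with a BKG series) so the whole pipeline is testable
  without clinical data.

## Worked example

```r
library(i131biokin)

params <- patient_parameters("average")   # cohort-average: 0.54 / 12.6 / 42.8 h, i23 = 0.21
tr <- solve_trajectory(params, c(1, 4, 24, 48, 72, 168))
print(tr)
#>      time_h  stomach bodyfluid  thyroid wholebody excretion
#> [1,]      1 0.276041  0.696899 0.004899  0.000029  0.018539
#> [2,]      4 0.005806  0.820408 0.032571  0.000874  0.126041
#> [3,]     24 0.000000  0.262220 0.111749  0.017856  0.525386
#> [4,]     48 0.000000  0.080084 0.101002  0.027000  0.633189
#> [5,]     72 0.000000  0.036073 0.074218  0.024234  0.637101
#> [6,]    168 0.000000  0.007433 0.017755  0.006576  0.514350
```

Each row is the fraction of the administered activity in each compartment:
the stomach empties within hours, the body fluid peaks early and drains,
and the thyroid rises to its maximum around 24 h before decaying — the
transient-equilibrium pattern seen on the scans.

Simulate one noisy patient and recover the parameters:

```r
cfg <- generator_config(n_patients = 1, noise_cov = 0.05, seed = 42)
sp  <- generate_patient(params, cfg, 1)
fit <- fit_patient(sp$raw, fit_config(seed = 42))
print(fit)
#> Fit for patient 'S1' (4387 objective evaluations)
#>   t_stomach 0.54 h  t_bfwb 11.02 h  t_thyroid 34.44 h  i23 0.22
#> AT agreement (N = 6): St 0.0002  Th 0.0226  BF+WB 0.0766  total 0.0461
```

With 5 % measurement noise on six scans, the recovered half-lives sit
within ~20 % of the generating values and AT_tot lands in the 0.02–0.08
range typical of the clinical fits. Other one-liners:

```r
effective_half_life(192, 450)             # 134.58 h -> the familiar ~135 h
summarize_cohort(cohort_parameter_table())  # published nine-patient means +/- SD
```

## Command line

```sh
Rscript inst/cli/i131biokin generate --output out --n-patients 9 --seed 1
Rscript inst/cli/i131biokin fit --input out/measurements.csv --output out/fits --verbose
Rscript inst/cli/i131biokin summarize --input out/fits/cohort.csv --output out
```

(`simulate` and `at` are also available; after installation the wrapper
lives at `system.file("cli", "i131biokin", package = "i131biokin")`.)

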