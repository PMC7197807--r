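test_that("generator_config validation", {
  expect_error(generator_config(n_patients = 0), ">= 1")
  expect_error(generator_config(noise_cov = -0.1), ">= 0")
  expect_error(generator_config(gain_range = c(0, 2)), "positive")
  expect_error(generator_config(source = "range",
                                ranges = list(t_stomach_h = c(1, 0.5),
                                              t_bfwb_h = c(1, 2),
                                              t_thyroid_h = c(1, 2),
                                              i23 = c(0, 1))), "ranges")
})

test_that("sample_parameters: fixed rows, degenerate ranges, determinism", {
  cfg <- generator_config(source = "fixed")
  p1 <- sample_parameters(cfg, 1)
  expect_equal(p1$half_lives$stomach_h, 0.50)
  expect_equal(p1$half_lives$bodyfluid_h, 15)
  expect_equal(p1$half_lives$thyroid_h, 35)
  expect_equal(p1$branching$i23, 0.18)
  expect_equal(p1$branching$i25, 0.82)
  expect_error(sample_parameters(cfg, 10), "only 9")

  deg <- generator_config(source = "range",
                          ranges = list(t_stomach_h = c(0.4, 0.4),
                                        t_bfwb_h = c(12, 12),
                                        t_thyroid_h = c(44, 44),
                                        i23 = c(0.2, 0.2)))
  pd <- sample_parameters(deg, 3)
  expect_equal(c(pd$half_lives$stomach_h, pd$half_lives$bodyfluid_h,
                 pd$half_lives$thyroid_h, pd$branching$i23),
               c(0.4, 12, 44, 0.2))

  rng <- generator_config(source = "range", seed = 9L)
  a <- sample_parameters(rng, 5); b <- sample_parameters(rng, 5)
  expect_identical(unclass(a$half_lives), unclass(b$half_lives))
  expect_identical(a$branching$i23, b$branching$i23)
})

test_that("range mode respects its bounds", {
  cfg <- generator_config(n_patients = 50, source = "range", seed = 3L)
  for (i in seq_len(50)) {
    p <- sample_parameters(cfg, i)
    expect_true(p$half_lives$stomach_h >= 0.30 &&
                  p$half_lives$stomach_h <= 1.30)
    expect_true(p$half_lives$bodyfluid_h >= 10 &&
                  p$half_lives$bodyfluid_h <= 15)
    expect_true(p$half_lives$thyroid_h >= 35 && p$half_lives$thyroid_h <= 50)
    expect_true(p$branching$i23 >= 0.04 && p$branching$i23 <= 0.50)
  }
})

test_that("degenerate noise settings reproduce the clean projection", {
  cfg <- generator_config(noise_cov = 0, gain_range = c(1, 1),
                          background_frac = 0, seed = 1L)
  truth <- patient_parameters(2)
  sp <- generate_patient(truth, cfg, 1)
  clean <- project_observables(sp$truth_trajectory, cfg$schedule)
  expect_equal(sp$raw$series, clean$series)
  expect_equal(sp$raw$bkg, rep(0, 6))
})

test_that("gain cancels through background subtraction + normalization", {
  truth <- patient_parameters(3)
  base <- generator_config(noise_cov = 0.05, gain_range = c(1, 1),
                           background_frac = 0.02, seed = 7L)
  wide <- generator_config(noise_cov = 0.05, gain_range = c(4, 4),
                           background_frac = 0.02, seed = 7L)
  n1 <- normalize_dataset(generate_patient(truth, base, 2)$raw)
  n4 <- normalize_dataset(generate_patient(truth, wide, 2)$raw)
  expect_equal(n1$series, n4$series, tolerance = 1e-12)
})

test_that("cohorts are reproducible and substream-independent", {
  cfg <- generator_config(n_patients = 3, seed = 11L)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(lapply(c1, function(s) s$raw$series),
                   lapply(c2, function(s) s$raw$series))
  # patient 2 alone equals patient 2 inside the cohort
  solo <- generate_patient(sample_parameters(cfg, 2), cfg, 2)
  expect_identical(solo$raw$series, c1[[2]]$raw$series)
})

test_that("empirical CoV of the noise matches noise_cov", {
  sched <- scan_schedule(1)
  cfg <- generator_config(schedule = sched, noise_cov = 0.05,
                          gain_range = c(1, 1), background_frac = 0,
                          seed = 5L)
  truth <- patient_parameters("average")
  n <- 10000L
  draws <- vapply(seq_len(n), function(i)
    generate_patient(truth, cfg, i)$raw$series$St[1], numeric(1))
  cov_hat <- sd(draws) / mean(draws)
  se <- 0.05 / sqrt(2 * n)
  expect_lt(abs(cov_hat - 0.05), 3 * se)
})

test_that("noise-free cohort round trip reproduces the generating means", {
  cfg <- generator_config(n_patients = 9, source = "fixed", noise_cov = 0,
                          background_frac = 0, seed = 2L)
  cohort <- generate_cohort(cfg)
  fits <- lapply(cohort, function(sp)
    fit_patient(sp$raw, quick_fit_config()))
  summ <- summarize_cohort(fits)
  expect_equal(round(summ$mean[["t_stomach_h"]], 2), 0.54)
  expect_equal(round(summ$sd[["t_stomach_h"]], 2), 0.32)
  expect_equal(round(summ$mean[["t_bfwb_h"]], 1), 12.6)
  expect_equal(round(summ$sd[["t_bfwb_h"]], 1), 1.8)
  expect_equal(round(summ$mean[["t_thyroid_h"]], 1), 42.8)
  expect_equal(round(summ$sd[["t_thyroid_h"]], 1), 5.1)
  expect_equal(round(summ$mean[["i23"]], 2), 0.21)
  expect_equal(round(summ$sd[["i23"]], 2), 0.14)
})

test_that("end-to-end: fit recovers thyroid half-life from one noisy patient", {
  cfg <- generator_config(noise_cov = 0.05, seed = 42L)
  truth <- patient_parameters("average")
  sp <- generate_patient(truth, cfg, 1)
  fr <- fit_patient(sp$raw, quick_fit_config(seed = 42L))
  expect_lt(abs(fr$theta[["t_thyroid_h"]] - 42.8) / 42.8, 0.20)
})
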