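test_that("decay_constant matches hand-computed rates and rejects bad input", {
  expect_equal(decay_constant(0.696, 1.0), 0.995901121494, tolerance = 1e-9)
  expect_equal(decay_constant(12.6, 0.21), 0.0115524530093, tolerance = 1e-9)
  expect_identical(decay_constant(12.6, 0.0), 0)
  expect_error(decay_constant(0, 0.5), "must be")
  expect_error(decay_constant(-3, 0.5), "must be")
  expect_error(decay_constant(10, 1.2), "fraction")
})

test_that("physical decay and parameter invariants hold", {
  pd <- physical_decay(192.5)
  expect_equal(pd$lambda_p * pd$half_life_h, log(2), tolerance = 1e-12)
  expect_error(physical_decay(-1))
  expect_error(branching_ratios(i23 = 0.3, i25 = 0.5), "i23 \\+ i25")
  expect_error(branching_ratios(i23 = 0.3, i42 = 0.5, i45 = 0.7),
               "i42 \\+ i45")
  expect_error(biological_half_lives(0, 12, 40))
  r <- transfer_rates(patient_parameters("average"))
  expect_true(all(r >= 0))
  expect_equal(unname(r[["lambda23"]] + r[["lambda25"]]), log(2) / 12.6)
})

test_that("rate matrix reproduces the kinetic equations and conserves mass", {
  p1 <- patient_parameters(1)
  A <- build_rate_matrix(p1)
  lp <- p1$physical$lambda_p
  # biological part moves activity without loss
  expect_equal(colSums(A + lp * diag(5)), rep(0, 5),
               tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(A["bodyfluid", "stomach"], log(2) / 0.50)
  expect_equal(A["bodyfluid", "wholebody"], 0.9 * log(2) / 15,
               tolerance = 1e-12)
  ref <- reference_adult_parameters()
  Aref <- build_rate_matrix(ref)
  expect_equal(Aref["bodyfluid", "stomach"], 0.995901121494,
               tolerance = 1e-9)
  # stomach has no inflow; excretion has no outflow besides decay
  expect_equal(Aref["stomach", -1], rep(0, 4), ignore_attr = TRUE)
  expect_equal(Aref[-5, 5], rep(0, 4), ignore_attr = TRUE)
})

test_that("solve_trajectory: identity at t = 0 and conservation without decay", {
  p <- patient_parameters(2, physical = physical_decay(1e12))
  q0 <- c(0.2, 0.3, 0.1, 0.25, 0.15)
  tr0 <- solve_trajectory(patient_parameters(2), 0, q0 = q0)
  expect_equal(tr0$q[1, ], q0, ignore_attr = TRUE)
  tr <- solve_trajectory(p, c(1, 24, 168), q0 = c(1, 0, 0, 0, 0))
  expect_equal(rowSums(tr$q), rep(1, 3), tolerance = 1e-8)
})

test_that("matrix exponential matches the RK4 oracle on patient 1", {
  times <- six_scans()$times_h
  p1 <- patient_parameters(1)
  exact <- solve_trajectory(p1, times)
  rk <- solve_trajectory_rk4(p1, times, step_h = 0.001)
  expect_lt(max(abs(exact$q - rk$q)), 1e-6)
})

test_that("RK4 shows 4th-order convergence and handles degenerate systems", {
  p <- patient_parameters(3)
  t <- 1
  exact <- solve_trajectory(p, t)$q
  err <- vapply(c(0.2, 0.1), function(h)
    max(abs(solve_trajectory_rk4(p, t, step_h = h)$q - exact)), numeric(1))
  expect_gt(err[1] / err[2], 12)   # ~16x for halved step
  expect_lt(err[1] / err[2], 20)
  # frozen system: enormous half-lives and no physical decay
  frozen <- biokinetic_parameters(
    biological_half_lives(1e14, 1e14, 1e14, 1e14),
    branching_ratios(i23 = 0.5), physical_decay(1e14))
  q0 <- c(0.4, 0.3, 0.2, 0.05, 0.05)
  trf <- solve_trajectory_rk4(frozen, c(10, 168), q0 = q0, step_h = 1)
  expect_equal(trf$q[2, ], q0, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("solver input validation", {
  p <- patient_parameters(1)
  expect_error(solve_trajectory(p, c(4, 1)), "sorted")
  expect_error(solve_trajectory(p, c(-1, 4)), "non-negative")
  expect_error(solve_trajectory(p, 4, q0 = c(-1, 0, 0, 0, 1)), "q0")
  expect_error(solve_trajectory_rk4(p, c(1, 4), step_h = 5), "spacing")
})

test_that("property: conservation, non-negativity, monotone stomach", {
  set.seed(42)
  times <- seq(0, 168, by = 8)
  for (rep in 1:25) {
    p <- random_params()
    tr <- solve_trajectory(p, times)
    expect_lt(max(abs(rowSums(tr$q) -
                        exp(-p$physical$lambda_p * times))), 1e-8)
    expect_true(all(tr$q >= -1e-12))
    expect_true(all(diff(tr$q[, "stomach"]) <= 1e-12))
  }
})

test_that("transient-equilibrium shape with cohort-average parameters", {
  tr <- solve_trajectory(patient_parameters("average"), c(1, 4, 24))
  th <- tr$q[, "thyroid"]
  expect_true(th[3] > th[2] && th[2] > th[1])
  expect_lt(tr$q[3, "stomach"], 0.01 * tr$q[1, "stomach"])
})

test_that("effective_half_life: worked example, limit and symmetry", {
  expect_equal(effective_half_life(192, 450), 134.579439252,
               tolerance = 1e-9)
  expect_equal(round(effective_half_life(192, 450)), 135)
  expect_equal(effective_half_life(100, 1e12), 100, tolerance = 1e-6)
  expect_equal(effective_half_life(100, 100), 50)
  expect_error(effective_half_life(-1, 10))
})
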