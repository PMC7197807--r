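# Shared fixtures: small parameter sets and noise-free datasets built in code.

six_scans <- function() scan_schedule(c(1, 4, 24, 48, 72, 168))

# Random-but-valid parameter draw for property tests (seeded by caller).
random_params <- function() {
  biokinetic_parameters(
    biological_half_lives(stomach_h = runif(1, 0.05, 5),
                          bodyfluid_h = runif(1, 1, 100),
                          thyroid_h = runif(1, 5, 500),
                          wholebody_h = runif(1, 1, 100)),
    branching_ratios(i23 = runif(1), i42 = runif(1)),
    physical_decay(runif(1, 50, 500)))
}

# Noise-free raw dataset generated from known parameters.
noisefree_set <- function(params, gain = 1, schedule = six_scans()) {
  clean <- project_observables(solve_trajectory(params, schedule$times_h),
                               schedule)
  measurement_set("truth", schedule,
                  st = gain * clean$series$St,
                  th = gain * clean$series$Th,
                  bfwb = gain * clean$series$BFWB)
}

# Fast fit configuration for tests that only need a decent optimum.
quick_fit_config <- function(seed = 1L)
  fit_config(grid_resolution = 5L, n_starts = 2L, n_random_starts = 1L,
             seed = seed)
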