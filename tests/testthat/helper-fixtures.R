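# Shared fixtures, built once per test run and memoized.

fixture_env <- new.env(parent = emptyenv())

# default-parameter bar simulation (calibration geometry, full duration)
default_bar_sim <- function() {
  if (is.null(fixture_env$bar_sim)) {
    cfg <- simulation_config(geometry = "bar", dt = 0.05)
    fixture_env$bar_sim <- run_simulation(cfg)
  }
  fixture_env$bar_sim
}

bar_frame_at <- function(sim, t) {
  Filter(function(f) abs(f$t - t) < 1e-9, sim$frames)[[1]]
}

# noiseless synthetic dataset at the default (calibrated) parameters,
# generated with the same forward discretization used by the GA tests
default_noiseless_dataset <- function(dt = 0.1) {
  key <- paste0("synth", dt)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- generate_profile_dataset(
      synthetic_config(noise = "none", dt = dt))
  }
  fixture_env[[key]]
}

# random deformation/growth states for constitutive oracles
random_deformation <- function() {
  F <- diag(3) + matrix(stats::runif(9, -0.3, 0.3), 3, 3)
  if (det(F) <= 0.2) F <- diag(3) + 0.1 * matrix(stats::runif(9, -1, 1), 3, 3)
  F
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}
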