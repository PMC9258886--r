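# small hand-built dataset for objective arithmetic
toy_dataset <- function(scale_density = 1, scale_length = 1) {
  keys <- data.frame(cohort = c(1, 2, 1, 2, 3, 1, 2, 3),
                     timepoint = c(1, 1, 2, 2, 2, 3, 3, 3))
  pos <- seq(0, 1, length.out = 10)
  prof <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    data.frame(cohort = keys$cohort[i], timepoint = keys$timepoint[i],
               normalized_position = pos,
               density = scale_density * (1e-5 + 1e-6 * keys$cohort[i] * pos))
  }))
  lens <- data.frame(timepoint = 1:3, length_um = scale_length * c(1390, 1997, 2390))
  experimental_dataset(prof, lens, "three_cohort")
}

test_that("objective arithmetic reproduces the balanced weighting", {
  ref <- toy_dataset()
  expect_equal(objective(ref, ref), 0)
  # doubling every density vector: each of the 8 relative norms is 1
  expect_equal(objective(toy_dataset(scale_density = 2), ref), 11,
               tolerance = 1e-12)
  # doubling every length: each of the 3 relative errors is 1
  expect_equal(objective(toy_dataset(scale_length = 2), ref), 11,
               tolerance = 1e-12)
  expect_error(
    objective(ref, experimental_dataset(
      within(ref$profiles, density <- 0 * density), ref$lengths,
      "three_cohort")),
    "degenerate")
})

test_that("objective is invariant to the order of the profile rows", {
  ref <- toy_dataset()
  shuffled <- ref
  set.seed(4)
  shuffled$profiles <- ref$profiles[sample(nrow(ref$profiles)), ]
  v1 <- objective(toy_dataset(2), ref)
  v2 <- objective(toy_dataset(2), shuffled)
  expect_equal(v1, v2)
})

test_that("dataset validation enforces the 8-profile layout", {
  ref <- toy_dataset()
  drop31 <- ref$profiles[!(ref$profiles$cohort == 3 & ref$profiles$timepoint == 2), ]
  expect_error(experimental_dataset(drop31, ref$lengths, "three_cohort"),
               "pairs")
  bad_len <- data.frame(timepoint = 1:3, length_um = c(1390, 1200, 2390))
  expect_error(experimental_dataset(ref$profiles, bad_len, "three_cohort"),
               "increasing")
})

test_that("evolve respects bounds, sorts destinations and creates no genomes from thin air when variation is off", {
  bounds <- genome_bounds()
  cfg0 <- ga_config(p_crossover = 0, p_mutation = 0)
  set.seed(8)
  pop <- matrix(runif(70, rep(bounds[, 1], each = 10), rep(bounds[, 2], each = 10)),
                10, dimnames = list(NULL, rownames(bounds)))
  pop[, c("d1", "d2", "d3")] <- t(apply(pop[, c("d1", "d2", "d3")], 1, sort))
  fit <- runif(10)
  nxt <- evolve(pop, fit, bounds, cfg0)
  # every child is a copy of some parent; the best survives
  expect_true(all(apply(nxt, 1, function(g)
    any(apply(pop, 1, function(q) all(q == g))))))
  expect_true(any(apply(nxt, 1, function(g) all(g == pop[which.min(fit), ]))))
  # with variation on, bounds and destination ordering hold over many generations
  cfg <- ga_config()
  for (gen in 1:60) {
    fit <- apply(pop, 1, function(g) sum((g / bounds[, 2] - 0.3)^2))
    pop <- evolve(pop, fit, bounds, cfg)
    expect_true(all(pop >= matrix(bounds[, 1], 10, 7, byrow = TRUE) - 1e-12))
    expect_true(all(pop <= matrix(bounds[, 2], 10, 7, byrow = TRUE) + 1e-12))
    expect_true(all(pop[, "d1"] <= pop[, "d2"] & pop[, "d2"] <= pop[, "d3"]))
  }
  expect_error(evolve(pop[0, , drop = FALSE], numeric(0), bounds, cfg), "empty")
})

test_that("the GA minimizes a toy sphere function to high accuracy", {
  bounds <- cbind(lower = c(0, 0), upper = c(1, 1))
  rownames(bounds) <- c("a", "b")
  target <- c(0.62, 0.34)
  set.seed(3)
  pop <- matrix(runif(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  cfg <- ga_config()
  best <- Inf
  for (gen in 1:50) {
    fit <- apply(pop, 1, function(g) sum((g - target)^2))
    best <- min(best, min(fit))
    pop <- evolve(pop, fit, bounds, cfg)
  }
  expect_lt(best, 1e-3)
})

test_that("calibration modes run end-to-end with a nonincreasing best trace", {
  gen <- default_noiseless_dataset(dt = 0.25)
  small <- ga_config(pop_size = 6, max_generations = 3, dt = 0.25,
                     n_elems = 30, n_points = 30)
  cal <- calibrate(gen$dataset, "three_cohort", small, seed = 2)
  expect_true(all(diff(cal$trace$best) <= 0))
  expect_true(all(cal$best_genome >= genome_bounds()[, 1]))
  expect_true(all(cal$best_genome <= genome_bounds()[, 2]))
  # leave-one-out: fit on the first two timepoints, then score the held-out
  # third timepoint; the prediction error must be finite and comparable
  keep <- gen$dataset$profiles$timepoint <= 2
  d2 <- experimental_dataset(gen$dataset$profiles[keep, ],
                             gen$dataset$lengths[1:2, ], "leave_out_t3",
                             strict = FALSE)
  cal2 <- calibrate(d2, "leave_out_t3", small, seed = 2)
  expect_true(is.finite(cal2$best_objective))
  p2 <- cortexfold:::genome_to_params(cal2$best_genome, model_parameters(),
                                      "leave_out_t3")
  sim2 <- forward_bar_model(p2, "three_cohort", n_elems = 30, dt = 0.25,
                            n_points = 30)
  full_fit <- objective(sim2, gen$dataset, n_points = 30)
  expect_true(is.finite(full_fit))
})

test_that("the single-cohort reduction needs a larger division rate to supply three cohorts' neurons", {
  gen <- default_noiseless_dataset(dt = 0.25)
  # summed-density dataset over the cohorts
  prof <- stats::aggregate(density ~ timepoint + normalized_position,
                           gen$dataset$profiles, sum)
  prof$cohort <- 1
  dsum <- experimental_dataset(prof, gen$dataset$lengths, "single_cohort",
                               strict = FALSE)
  cfg <- ga_config(pop_size = 8, max_generations = 8, dt = 0.25,
                   n_elems = 30, n_points = 30)
  cal <- calibrate(dsum, "single_cohort", cfg, seed = 3)
  expect_gt(cal$best_genome[["Gc"]], 1.41e-5)
})

test_that("the objective is much more sensitive to the division rate than to diffusion", {
  gen <- default_noiseless_dataset(dt = 0.25)
  truth <- gen$truth$genome
  # same discretization as the generator, so the truth scores exactly zero
  cfg <- ga_config(dt = 0.25, n_elems = 60, n_points = 60)
  scan <- sensitivity_scan(truth, c("Gc", "D"), gen$dataset,
                           rel_grid = c(0.8, 1, 1.2), config = cfg)
  # the exact center is the generating truth: a local minimum of the grid
  center <- scan$f_obj[scan$f1 == 1 & scan$f2 == 1]
  expect_lt(center, min(scan$f_obj[scan$f1 != 1 | scan$f2 != 1]))
  along_gc <- range(scan$f_obj[scan$f2 == 1])
  along_d <- range(scan$f_obj[scan$f1 == 1])
  expect_gt(diff(along_gc), 2 * diff(along_d))
})
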