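test_that("pointwise cohort flux combines gated advection and Fickian diffusion", {
  p <- model_parameters()
  # no cells: only diffusion survives
  g <- c(1e-7, 0, 0)
  expect_equal(cohort_flux(0, g, diag(3), c(1, 0, 0), 50, 1, p), p$D * g)
  # at the destination the velocity vanishes regardless of activation
  expect_equal(cohort_flux(p$c0, c(0, 0, 0), diag(3), c(1, 0, 0),
                           p$delta_iv[1], 1, p), c(0, 0, 0))
  # saturated activation and velocity well inside the destination
  ci <- 100 * p$c0
  fl <- cohort_flux(ci, c(0, 0, 0), diag(3), c(1, 0, 0), 10, 1, p)
  expect_equal(fl, -ci * migration_activation(ci, p) *
                 velocity_magnitude(10, 1, p) * c(1, 0, 0), tolerance = 1e-12)
  # deep inside the destination both gates are saturated: flux ~ -c v/2
  expect_lt(abs(fl[1] + ci * 0.5 * p$v_base) / abs(fl[1]), 0.15)
  expect_error(cohort_flux(ci, c(0, 0, 0), diag(3), c(0, 0, 0), 10, 1, p),
               "degenerate fiber")
})

test_that("total density sums cohorts pointwise", {
  m <- cbind(c(1, 2), c(3, 4), c(5, 6))
  expect_equal(total_density(m), c(9, 12))
  expect_equal(total_density(c(2, 3)), c(2, 3))
})

test_that("pure dilution: without source, velocity and diffusion the referential density is frozen", {
  p <- model_parameters(Gc = 0, v_base = 0, D = 0)
  mesh <- make_bar_mesh(239, 30)
  c0 <- matrix(0, 31, 3)
  c0[, 1] <- 1e-5 * exp(-((mesh$x - 100) / 40)^2)
  # a deformed state (homogeneous growth), J = 2 everywhere
  g <- list(th_par = rep(2, 30), th_perp = rep(1, 30))
  mech <- solve_equilibrium(mesh, g, p)
  out <- advance_density(mesh, c0, mech, 0.5, 0.5, p)
  expect_equal(out$c0, c0, tolerance = 1e-12)
  expect_equal(out$clipped, c(0, 0, 0))
  # spatial density is the referential density diluted by J
  fr <- cortexfold:::frame_from_state(mesh, mech, out$c0, 0.5, p)
  expect_equal(fr$c_spatial[, 1], c0[, 1] / 2, tolerance = 1e-12)
})

test_that("diffusion-only run matches the Neumann heat-equation series solution", {
  p <- model_parameters(Gc = 0, v_base = 0)
  mesh <- make_bar_mesh(239, 60)
  L <- 239
  a0 <- 2e-5; a1 <- 1e-5
  c_init <- a0 + a1 * cos(pi * mesh$x / L)
  c0 <- cbind(c_init, 0 * c_init, 0 * c_init)
  dt <- 0.002
  tend <- 0.1
  for (s in seq_len(round(tend / dt)))
    c0 <- advance_density(mesh, c0, NULL, s * dt, dt, p)$c0
  exact <- a0 + a1 * cos(pi * mesh$x / L) * exp(-p$D * (pi / L)^2 * tend)
  l2 <- sqrt(mean((c0[, 1] - exact)^2)) / sqrt(mean(exact^2))
  expect_lt(l2, 0.01)
})

test_that("zero-flux transport conserves cell number to solver accuracy", {
  p <- model_parameters(Gc = 0)   # full advection + diffusion, no source
  mesh <- make_bar_mesh(239, 40)
  set.seed(21)
  c0 <- cbind(1e-5 * runif(41), 5e-6 * runif(41), 2e-6 * runif(41))
  g <- list(th_par = rep(1.5, 40), th_perp = rep(1, 40))
  mech <- solve_equilibrium(mesh, g, p)
  h <- diff(mesh$x)
  mass <- function(cc) sum((cc[-1, ] + cc[-41, ]) / 2 * h)
  m0 <- mass(c0)
  for (s in 1:10) {
    out <- advance_density(mesh, c0, mech, s * 0.05, 0.05, p)
    m1 <- mass(out$c0) - sum(out$clipped)
    expect_lt(abs(m1 - m0) / m0, 1e-6)
    c0 <- out$c0
    m0 <- mass(c0)
  }
})

test_that("2-D transport conserves cell number and feeds the ventricular source", {
  p <- model_parameters()
  mesh <- make_halfcircle_mesh(239, 100)
  mesh$fem_pre <- cortexfold:::precompute_fem2d(mesh)
  nn <- nrow(mesh$nodes)
  c0 <- matrix(0, nn, 3)
  # two source steps, then two source-free steps with conservation
  for (s in 1:2) c0 <- advance_density(mesh, c0, NULL, s * 0.05, 0.05, p)$c0
  expect_gt(max(c0[, 1]), 0)
  # density appears in the ventricular zone first
  r <- sqrt(rowSums(mesh$nodes^2))
  expect_gt(mean(c0[r < 0.3 * 239, 1]), mean(c0[r > 0.6 * 239, 1]))
  p0 <- model_parameters(Gc = 0)
  M <- cortexfold:::mass_matrix_2d(mesh, mesh$fem_pre)$M
  mass <- function(cc) sum(as.numeric(M %*% cc))
  m0 <- mass(c0)
  for (s in 1:3) {
    out <- advance_density(mesh, c0, NULL, 1 + s * 0.05, 0.05, p0)
    expect_lt(abs(mass(out$c0) - sum(out$clipped) - m0) / m0, 1e-6)
    c0 <- out$c0
    m0 <- mass(c0)
  }
})

test_that("the default run settles cohorts inside-out by birth order", {
  sim <- default_bar_sim()
  fr <- bar_frame_at(sim, 27)
  x <- sim$mesh$x
  mean_pos <- vapply(1:3, function(i)
    sum(x * fr$c0[, i]) / sum(fr$c0[, i]), numeric(1))
  expect_true(mean_pos[1] < mean_pos[2])
  expect_true(mean_pos[2] < mean_pos[3])
  # clipping, if any, stays far below 0.1% of the cell number
  h <- diff(x)
  total <- sum((rowSums(fr$c0)[-1] + rowSums(fr$c0)[-length(x)]) / 2 * h)
  expect_lt(sum(sim$clipped), 1e-3 * total)
})
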