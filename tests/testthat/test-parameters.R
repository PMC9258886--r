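test_that("defaults carry the calibrated ferret parameter set", {
  p <- model_parameters()
  expect_equal(p$R0, 239)
  expect_equal(p$delta_x, 0.2 * 239)
  expect_equal(p$delta_it, c(0, 3, 6))
  expect_equal(p$delta_iv, c(191.6, 210.7, 222.7))
  expect_equal(p$Gc, 1.41e-5)
  expect_equal(p$v_base, 1472.2)
  expect_equal(p$D, 31612.6)
  expect_equal(p$k_s, 202950)
  expect_equal(p$tau, 27)
  expect_equal(p$L_s, 9.3)
})

test_that("parameter validation rejects inconsistent inputs", {
  expect_error(model_parameters(nu = 0.5), "nu")
  expect_error(model_parameters(delta_iv = c(200, 195, 210)), "delta_iv")
  expect_error(model_parameters(beta_mu = 0.5), "beta_mu")
  expect_error(model_parameters(v_base = -1), "v_base")
  expect_error(smoothed_heaviside(0, alpha = -1), "alpha")
})

test_that("smoothed heaviside is a logistic with the right limits", {
  expect_equal(smoothed_heaviside(0, 3.7), 0.5)
  expect_equal(smoothed_heaviside(1 / 0.3, 0.3), exp(1) / (1 + exp(1)),
               tolerance = 1e-12)
  expect_equal(smoothed_heaviside(1e4, 0.1), 1)
  expect_equal(smoothed_heaviside(-1e4, 0.1), 0)
  x <- seq(-50, 50, length.out = 401)
  expect_true(all(diff(smoothed_heaviside(x, 0.2)) > 0))
})

test_that("migration activation is the logistic of normalized excess density", {
  p <- model_parameters()
  expect_equal(migration_activation(p$c0, p), 0.5)
  expect_lt(migration_activation(0, p), 0.5)
  # c = 21*c0 with alpha_c = 0.1 puts the logistic argument at 2
  expect_equal(migration_activation(21 * p$c0, p), plogis(2),
               tolerance = 1e-12)
})

test_that("neurogenesis profiles peak in the ventricular zone and at the birth dates", {
  p <- model_parameters()
  expect_equal(neurogenesis_spatial(p$delta_x, p), 0.5)
  expect_equal(neurogenesis_spatial(0, p), plogis(0.05 * 47.8), tolerance = 1e-12)
  expect_gt(neurogenesis_spatial(0, p), 0.9)
  expect_lt(neurogenesis_spatial(p$R0, p), 1e-4)
  for (i in 1:3) {
    expect_equal(neurogenesis_temporal(p$delta_it[i], i, p), 1)
    expect_equal(neurogenesis_temporal(p$delta_it[i] + p$epsilon, i, p), 0.5)
    expect_equal(neurogenesis_temporal(p$delta_it[i] + 10 * p$epsilon, i, p),
                 1 / 101)
  }
})

test_that("migration velocity vanishes exactly at the destination and saturates at half the baseline", {
  p <- model_parameters()
  for (i in 1:3) expect_equal(velocity_magnitude(p$delta_iv[i], i, p), 0)
  expect_equal(velocity_magnitude(0, 1, p), 0.5 * 1472.2, tolerance = 1e-3)
  expect_equal(velocity_magnitude(2 * p$delta_iv[1], 1, p), -0.5 * 1472.2,
               tolerance = 1e-3)
})

test_that("growth and stiffness profiles plateau at the stated cortical/subcortical values", {
  p <- model_parameters(beta_k = 2, beta_mu = 3)
  k0 <- growth_coefficients(0, p)
  expect_equal(k0$k_par, p$k_s, tolerance = 1e-6)
  expect_equal(k0$k_perp, p$k_s, tolerance = 1e-6)
  kc <- growth_coefficients(p$delta_k + 50, p)
  expect_equal(kc$k_par, p$k_s / 2, tolerance = 1e-6)
  expect_equal(kc$k_perp, 2 * p$k_s, tolerance = 1e-6)
  km <- growth_coefficients(p$delta_k, p)
  expect_equal(km$k_par, p$k_s * (1 + 0.5 * (1 / 2 - 1)))
  expect_equal(km$k_perp, p$k_s * (1 + 0.5 * (2 - 1)))
  expect_equal(shear_modulus(0, p), 1, tolerance = 1e-6)
  expect_equal(shear_modulus(p$R0, p), 3, tolerance = 1e-3)
  expect_equal(shear_modulus(p$delta_mu, p), 2)
  # uniform Poisson ratio: L tracks mu
  expect_equal(lame_L(p$R0, p) / shear_modulus(p$R0, p), p$L_s / p$mu_s)
  # beta_k = beta_mu = 1 means a homogeneous domain
  ph <- model_parameters(beta_k = 1, beta_mu = 1)
  r <- seq(0, 2 * ph$R0, length.out = 100)
  expect_equal(growth_coefficients(r, ph)$k_par, rep(ph$k_s, 100))
  expect_equal(shear_modulus(r, ph), rep(ph$mu_s, 100))
})

test_that("profile functions are bounded and monotone between plateaus", {
  p <- model_parameters(beta_k = 1.5)
  r <- seq(0, 2 * p$R0, length.out = 500)
  gx <- neurogenesis_spatial(r, p)
  expect_true(all(gx > 0 & gx < 1))
  expect_true(all(diff(gx) < 0))
  mu <- shear_modulus(r, p)
  expect_true(all(diff(mu) >= 0))
  expect_true(all(mu >= p$mu_s & mu <= p$beta_mu * p$mu_s))
  v <- velocity_magnitude(r, 2, p)
  expect_true(all(diff(v) < 0))
  expect_true(all(abs(v) <= 0.5 * p$v_base))
})

test_that("yaml round trip preserves parameters and rejects unknown keys", {
  p <- model_parameters(Gc = 5e-6, beta_k = 1.5)
  f <- tempfile(fileext = ".yaml")
  write_parameters(p, f)
  q <- read_parameters(f)
  expect_equal(unclass(q), unclass(p))
  writeLines("not_a_parameter: 1", f)
  expect_error(read_parameters(f), "unknown parameter")
})
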