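test_that("zero growth leaves both geometries undeformed and stress-free", {
  p <- model_parameters()
  mb <- make_bar_mesh(239, 20)
  g0 <- list(th_par = rep(1, 20), th_perp = rep(1, 20))
  sb <- solve_equilibrium(mb, g0, p)
  expect_true(sb$converged)
  expect_equal(sb$u, rep(0, 21))
  expect_equal(sb$Txx, rep(0, 20))
  mh <- make_halfcircle_mesh(239, 120)
  gh <- list(th_par = rep(1, mh$n_elems), th_perp = rep(1, mh$n_elems))
  sh <- solve_equilibrium(mh, gh, p)
  expect_true(sh$converged)
  expect_equal(max(abs(sh$u)), 0)
})

test_that("homogeneous axial bar growth is stress-free with length R0 * (1 + k c)", {
  p <- model_parameters()
  m <- make_bar_mesh(239, 30)
  th <- 1 + p$k_s * 1e-5         # homogeneous density, k_perp = 0
  g <- list(th_par = rep(th, 30), th_perp = rep(1, 30))
  s <- solve_equilibrium(m, g, p)
  expect_true(s$converged)
  expect_equal(239 + s$u[31], 239 * th, tolerance = 1e-8)
  expect_equal(max(abs(s$Txx)), 0, tolerance = 1e-8)
  expect_equal(max(abs(s$Tyy)), 0, tolerance = 1e-8)
  expect_equal(s$Je, rep(1, 30), tolerance = 1e-10)
})

test_that("free homogeneous isotropic growth of the half disc is stress-free scaling", {
  p <- model_parameters(beta_mu = 1, beta_k = 1)
  m <- make_halfcircle_mesh(239, 150)
  g <- 1.6
  gr <- list(th_par = rep(g, m$n_elems), th_perp = rep(g, m$n_elems))
  s <- solve_equilibrium(m, gr, p, u_prev = (g - 1) * m$nodes)
  expect_true(s$converged)
  expect_equal(s$u, (g - 1) * m$nodes, tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(s$Je, rep(1, m$n_elems), tolerance = 1e-8)
  expect_equal(s$J, rep(g^3, m$n_elems), tolerance = 1e-8)  # thickness grows too
})

test_that("affine displacement fields produce self-equilibrated uniform stress (patch test)", {
  p <- model_parameters(beta_mu = 1)
  m <- make_halfcircle_mesh(239, 80)
  m$fem_pre <- cortexfold:::precompute_fem2d(m)
  A <- matrix(c(0.08, 0.03, -0.02, 0.05), 2, 2)
  u <- m$nodes %*% t(A)
  gr <- list(th_par = rep(1, m$n_elems), th_perp = rep(1, m$n_elems))
  asm <- cortexfold:::assemble_2d(m, gr, p, u)
  # interior nodes (not on any boundary) must carry zero residual
  bdry <- unique(c(m$boundary$symmetry, m$boundary$surface))
  interior <- setdiff(seq_len(nrow(m$nodes)), bdry)
  dofs <- c(2 * interior - 1, 2 * interior)
  expect_lt(max(abs(asm$R[dofs])), 1e-9 * max(abs(asm$R)))
})

test_that("the stress of a rotated elastic state is the rotated stress", {
  set.seed(5)
  Fe <- random_deformation()
  th <- 0.7
  Q <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  T1 <- cauchy_stress(Q %*% Fe, 1.3, 9.3)
  T2 <- Q %*% cauchy_stress(Fe, 1.3, 9.3) %*% t(Q)
  expect_equal(T1, T2, tolerance = 1e-12)
})

test_that("the 2-D tangent is the exact derivative of the residual", {
  p <- model_parameters()
  m <- make_halfcircle_mesh(239, 24)
  m$fem_pre <- cortexfold:::precompute_fem2d(m)
  set.seed(9)
  gr <- list(th_par = runif(m$n_elems, 1, 1.3),
             th_perp = runif(m$n_elems, 1, 1.3))
  u <- matrix(rnorm(2 * nrow(m$nodes), 0, 1.5), ncol = 2)
  asm <- cortexfold:::assemble_2d(m, gr, p, u)
  h <- 1e-6
  for (d in sample(2 * nrow(m$nodes), 8)) {
    up <- as.vector(t(u)); up[d] <- up[d] + h
    um <- as.vector(t(u)); um[d] <- um[d] - h
    Rp <- cortexfold:::assemble_2d(m, gr, p, matrix(up, ncol = 2, byrow = TRUE))$R
    Rm <- cortexfold:::assemble_2d(m, gr, p, matrix(um, ncol = 2, byrow = TRUE))$R
    expect_equal(as.numeric(asm$K[, d]), (Rp - Rm) / (2 * h),
                 tolerance = 1e-4)
  }
})
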