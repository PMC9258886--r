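test_that("growth tensor has the prescribed transversely isotropic eigenstructure", {
  expect_equal(growth_tensor(0, 1e5, 1e5, c(1, 0, 0)), diag(3))
  # calibrated subcortical growth at a typical density, no tangential growth
  Fg <- growth_tensor(1e-5, 202950, 0, c(1, 0, 0))
  expect_equal(Fg, diag(c(3.0295, 1, 1)), tolerance = 1e-12)
  set.seed(42)
  for (rep in 1:20) {
    N <- random_unit_vector()
    c <- runif(1, 0, 2e-5)
    kp <- runif(1, 0, 3e5); kq <- runif(1, 0, 3e5)
    Fg <- growth_tensor(c, kp, kq, N)
    expect_equal(det(Fg), (1 + kp * c) * (1 + kq * c)^2, tolerance = 1e-10)
    # N is an eigenvector with the parallel stretch
    expect_equal(as.numeric(Fg %*% N), (1 + kp * c) * N, tolerance = 1e-10)
    # rotation about N commutes with Fg
    ax <- N
    th <- runif(1, 0, 2 * pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
                byrow = TRUE)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    expect_equal(R %*% Fg, Fg %*% R, tolerance = 1e-10)
  }
  expect_error(growth_tensor(1, -2, 0, c(1, 0, 0)), "degenerate")
  expect_error(growth_tensor(1e-5, 1e5, 0, c(1, 1, 0)), "unit")
})

test_that("elastic decomposition satisfies F = Fe Fg and J = Je Jg", {
  st <- elastic_decomposition(diag(c(2, 1, 1)), diag(c(2, 1, 1)))
  expect_equal(st$Fe, diag(3))
  expect_equal(st$Je, 1)
  st2 <- elastic_decomposition(diag(3), diag(c(2, 1, 1)))
  expect_equal(st2$Fe, diag(c(0.5, 1, 1)))
  expect_equal(st2$Je, 0.5)
  set.seed(7)
  for (rep in 1:25) {
    F <- random_deformation()
    Fg <- growth_tensor(runif(1, 0, 1e-5), 2e5, 1e5, random_unit_vector())
    st <- elastic_decomposition(F, Fg)
    expect_equal(st$J, st$Je * st$Jg, tolerance = 1e-12 * abs(st$J))
    expect_equal(st$Fe %*% st$Fg, F, tolerance = 1e-10)
    expect_equal(st$Be, t(st$Be))
    expect_true(all(eigen(st$Ce, symmetric = TRUE)$values > 0))
  }
  expect_error(elastic_decomposition(diag(c(-1, 1, 1)), diag(3)), "positive")
})

test_that("strain energy vanishes in the reference state and matches its isochoric reduction", {
  expect_equal(strain_energy(diag(3), 1, 1, 9.3), 0)
  lam <- 1.3
  Ce <- diag(c(lam^2, 1 / lam, 1 / lam))
  expect_equal(strain_energy(Ce, 1, 2, 9.3), 2 / 2 * (sum(diag(Ce)) - 3),
               tolerance = 1e-12)
  expect_error(strain_energy(diag(3), -1, 1, 9.3), "positive")
})

test_that("cauchy stress agrees with numerical differentiation of the free energy", {
  # push-forward of dpsi/dFe must reproduce the closed-form stress
  set.seed(13)
  h <- 1e-6
  for (rep in 1:100) {
    Fe <- random_deformation()
    mu <- runif(1, 0.5, 3); L <- runif(1, 5, 12)
    T <- cauchy_stress(Fe, mu, L)
    expect_equal(T, t(T), tolerance = 1e-10)
    P <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      Fp <- Fe; Fp[i, j] <- Fp[i, j] + h
      Fm <- Fe; Fm[i, j] <- Fm[i, j] - h
      P[i, j] <- (strain_energy(crossprod(Fp), det(Fp), mu, L) -
                  strain_energy(crossprod(Fm), det(Fm), mu, L)) / (2 * h)
    }
    T_fd <- P %*% t(Fe) / det(Fe)
    expect_equal(T, T_fd, tolerance = 1e-5)
  }
})

test_that("only elastic deformation induces stress", {
  expect_equal(cauchy_stress(diag(3), 1, 9.3), matrix(0, 3, 3))
  set.seed(3)
  for (rep in 1:10) {
    Fg <- growth_tensor(runif(1, 0, 1e-5), 2e5, 4e5, random_unit_vector())
    st <- elastic_decomposition(Fg, Fg)   # F = Fg, fully relaxed growth
    expect_equal(cauchy_stress(st$Fe, 1, 9.3), matrix(0, 3, 3),
                 tolerance = 1e-12)
  }
})

test_that("small-strain limit linearizes to lambda tr(eps) I + 2 mu eps", {
  set.seed(11)
  eps_mag <- 1e-6
  H <- matrix(rnorm(9), 3, 3)
  E <- eps_mag * (H + t(H)) / 2
  mu <- 1.7; L <- 9.3
  T <- cauchy_stress(diag(3) + E, mu, L)
  T_lin <- L * sum(diag(E)) * diag(3) + 2 * mu * E
  expect_equal(T, T_lin, tolerance = 1e-5 * eps_mag / 1e-6)
})
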