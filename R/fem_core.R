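# Quasi-static mechanical equilibrium, div T = 0, with a growth-prescribed
# Fg per quadrature point. Total-Lagrangian displacement elements with a
# full Newton solve and analytic consistent tangent. Two geometries:
#
#  * bar: the lateral faces carry symmetry conditions, so the lateral total
#    stretch is 1 and the only unknown is the axial displacement. F, Fg, Fe
#    are still full 3x3 (diagonal) tensors at each point.
#  * halfcircle: 2 dofs per node; the out-of-plane direction carries zero
#    ELASTIC strain (Fe_33 = 1): the thickness follows the growth stretch
#    freely, so out-of-plane growth neither stores energy nor loads the
#    in-plane response.

#' Solve mechanical equilibrium for a grown configuration
#'
#' Newton iteration for the displacement field that balances internal
#' stresses given the per-element growth state, starting from
#' \code{u_prev}. Convergence is declared when the residual force norm
#' drops below \code{rtol} times a reference internal-force scale.
#'
#' @param mesh A \code{cortexfold_mesh} (bar or halfcircle).
#' @param growth List with per-element growth stretches \code{th_par},
#'   \code{th_perp} (fiber-parallel / perpendicular, both > 0).
#' @param params \code{cortexfold_params} (supplies the modulus profiles).
#' @param u_prev Previous displacement (bar: numeric per node; halfcircle:
#'   n_nodes x 2 matrix). Defaults to zero.
#' @param rtol Relative residual tolerance.
#' @param max_iter Maximum Newton iterations before signaling
#'   non-convergence.
#' @return A list of class \code{mechanical_state}: \code{u},
#'   \code{converged}, \code{iterations}, per-element \code{F} components,
#'   \code{J}, \code{Je}, and Cauchy stress components.
#' @export
solve_equilibrium <- function(mesh, growth, params, u_prev = NULL,
                              rtol = 1e-8, max_iter = 25) {
  switch(mesh$type,
         bar = solve_equilibrium_bar(mesh, growth, params, u_prev, rtol, max_iter),
         halfcircle = solve_equilibrium_2d(mesh, growth, params, u_prev, rtol, max_iter),
         stop("unknown mesh type: ", mesh$type, call. = FALSE))
}

# ---------------------------------------------------------------- bar ----

# element midpoints (referential radius used by all material profiles)
bar_midpoints <- function(mesh) (mesh$x[-1] + mesh$x[-length(mesh$x)]) / 2

# scatter-add with duplicate indices summed (plain R indexing drops them)
scatter_add <- function(n, idx, vals) {
  as.numeric(Matrix::sparseMatrix(i = idx, j = rep(1L, length(idx)),
                                  x = vals, dims = c(n, 1L)))
}

solve_equilibrium_bar <- function(mesh, growth, params, u_prev, rtol, max_iter) {
  n_el <- mesh$n_elems
  nn <- n_el + 1L
  h <- diff(mesh$x)
  thp <- growth$th_par
  tht <- growth$th_perp
  stopifnot(length(thp) == n_el, all(thp > 0), all(tht > 0))
  r_mid <- bar_midpoints(mesh)
  mu <- shear_modulus(r_mid, params)
  L <- lame_L(r_mid, params)
  Jg <- thp * tht^2

  u <- if (is.null(u_prev)) numeric(nn) else u_prev
  u[1] <- 0
  free <- 2:nn
  f_ref <- max(params$mu_s, 1)
  converged <- FALSE
  iter <- 0L
  # predictor: if starting from zero with large growth, seed with Fe = 1
  for (iter in seq_len(max_iter)) {
    Fxx <- 1 + diff(u) / h
    if (any(Fxx <= 0)) stop("element inversion in bar solve", call. = FALSE)
    Fexx <- Fxx / thp
    Je <- Fexx / tht^2
    lnJe <- log(Je)
    Pexx <- mu * Fexx + (L * lnJe - mu) / Fexx
    Pxx <- Jg * Pexx / thp
    Axx <- (Jg / thp^2) * (mu + (mu - L * lnJe) / Fexx^2 + L / Fexx^2)
    # residual: R_a = sum_e Pxx * dN_a/dX * h  (dN = -1/h left, +1/h right)
    R <- numeric(nn)
    R[1:n_el] <- R[1:n_el] - Pxx
    R[2:nn] <- R[2:nn] + Pxx
    f_scale <- max(f_ref, max(abs(Pxx)))
    if (max(abs(R[free])) <= rtol * f_scale) { converged <- TRUE; break }
    k <- Axx / h
    # tridiagonal stiffness on free dofs (small, solved dense)
    if (n_el == 1L) {
      du <- -R[2] / k[1]
    } else {
      K <- matrix(0, nn - 1, nn - 1)
      diag(K) <- c(k[seq_len(n_el - 1)] + k[2:n_el], k[n_el])
      K[cbind(seq_len(n_el - 1), seq_len(n_el - 1) + 1L)] <- -k[2:n_el]
      K[cbind(seq_len(n_el - 1) + 1L, seq_len(n_el - 1))] <- -k[2:n_el]
      du <- solve(K, -R[free])
    }
    u[free] <- u[free] + du
  }
  Fxx <- 1 + diff(u) / h
  Fexx <- Fxx / thp
  Je <- Fexx / tht^2
  Txx <- (mu * Fexx^2 + L * log(Je) - mu) / Je
  Tyy <- (mu / tht^2 + L * log(Je) - mu) / Je
  structure(list(u = u, converged = converged, iterations = iter,
                 Fxx = Fxx, J = Fxx, Je = Je, Txx = Txx, Tyy = Tyy,
                 growth = growth),
            class = "mechanical_state")
}

# --------------------------------------------------------- half circle ----

# Precompute reference-geometry quantities reused every assembly:
# per gauss point: dN/dX (n_el x 4 x 2) and weights w*detJ.
precompute_fem2d <- function(mesh) {
  gp <- quad_gauss()
  X <- mesh$nodes
  el <- mesh$elements
  n_el <- nrow(el)
  pre <- vector("list", 4)
  for (q in 1:4) {
    dN <- quad_dN(gp$xi[q, 1], gp$xi[q, 2])
    J11 <- J12 <- J21 <- J22 <- numeric(n_el)
    for (a in 1:4) {
      xa <- X[el[, a], 1]; ya <- X[el[, a], 2]
      J11 <- J11 + xa * dN[a, 1]; J12 <- J12 + xa * dN[a, 2]
      J21 <- J21 + ya * dN[a, 1]; J22 <- J22 + ya * dN[a, 2]
    }
    detJ <- J11 * J22 - J12 * J21
    # dN/dX_i = dN/dxi_k * (Jinv)_ki ; Jinv = 1/det * [J22 -J12; -J21 J11]
    dNdX <- array(0, c(n_el, 4, 2))
    for (a in 1:4) {
      dNdX[, a, 1] <- (dN[a, 1] * J22 - dN[a, 2] * J21) / detJ
      dNdX[, a, 2] <- (-dN[a, 1] * J12 + dN[a, 2] * J11) / detJ
    }
    # referential radius and shape values at the gauss point
    Nsh <- quad_shape(gp$xi[q, 1], gp$xi[q, 2])
    xg <- Nsh[1] * X[el[, 1], 1] + Nsh[2] * X[el[, 2], 1] +
          Nsh[3] * X[el[, 3], 1] + Nsh[4] * X[el[, 4], 1]
    yg <- Nsh[1] * X[el[, 1], 2] + Nsh[2] * X[el[, 2], 2] +
          Nsh[3] * X[el[, 3], 2] + Nsh[4] * X[el[, 4], 2]
    pre[[q]] <- list(dNdX = dNdX, wdetJ = gp$w[q] * detJ, Nsh = Nsh,
                     r = sqrt(xg^2 + yg^2))
  }
  # 5th entry: element-mean gradient operator (B-bar) used to integrate the
  # volumetric part of the energy once per element, which avoids the
  # volumetric locking of fully integrated quads at near-incompressibility
  area <- pre[[1]]$wdetJ + pre[[2]]$wdetJ + pre[[3]]$wdetJ + pre[[4]]$wdetJ
  dNbar <- array(0, c(n_el, 4, 2))
  rbar <- numeric(n_el)
  for (q in 1:4) {
    dNbar <- dNbar + pre[[q]]$dNdX * as.vector(pre[[q]]$wdetJ)
    rbar <- rbar + pre[[q]]$r * pre[[q]]$wdetJ
  }
  dNbar <- dNbar / as.vector(area)
  pre[[5]] <- list(dNdX = dNbar, wdetJ = area, Nsh = rep(0.25, 4),
                   r = rbar / area)
  # sparse triplet pattern for the 8x8 element blocks (dofs: 2*node-1, 2*node)
  edof <- matrix(0L, n_el, 8)
  for (a in 1:4) {
    edof[, 2 * a - 1] <- 2L * el[, a] - 1L
    edof[, 2 * a] <- 2L * el[, a]
  }
  ii <- matrix(0L, n_el, 64); jj <- matrix(0L, n_el, 64)
  k <- 0L
  for (a in 1:8) for (b in 1:8) {
    k <- k + 1L
    ii[, k] <- edof[, a]; jj[, k] <- edof[, b]
  }
  list(gp = pre, edof = edof, ii = as.vector(ii), jj = as.vector(jj),
       n_dof = 2L * nrow(X))
}

# deformation gradient components at one gauss point for all elements
f2d_at_gp <- function(ux, uy, el, dNdX) {
  F11 <- rep(1, nrow(el)); F12 <- numeric(nrow(el))
  F21 <- numeric(nrow(el)); F22 <- rep(1, nrow(el))
  for (a in 1:4) {
    F11 <- F11 + ux[el[, a]] * dNdX[, a, 1]
    F12 <- F12 + ux[el[, a]] * dNdX[, a, 2]
    F21 <- F21 + uy[el[, a]] * dNdX[, a, 1]
    F22 <- F22 + uy[el[, a]] * dNdX[, a, 2]
  }
  list(F11 = F11, F12 = F12, F21 = F21, F22 = F22)
}

# Assemble the internal-force residual and consistent tangent stiffness of
# the half-circle geometry at displacement u. Returns list(R, K, bad).
assemble_2d <- function(mesh, growth, params, u, pre = mesh$fem_pre) {
  if (is.null(pre)) pre <- precompute_fem2d(mesh)
  n_el <- nrow(mesh$elements)
  el <- mesh$elements
  thp <- growth$th_par; tht <- growth$th_perp
  Nx <- mesh$N[, 1]; Ny <- mesh$N[, 2]
  r_c <- sqrt(rowSums((mesh$nodes[el[, 1], ] + mesh$nodes[el[, 2], ] +
                       mesh$nodes[el[, 3], ] + mesh$nodes[el[, 4], ])^2 / 16))
  mu <- shear_modulus(r_c, params)
  L <- lame_L(r_c, params)
  ith <- 1 / thp - 1 / tht
  Gi11 <- 1 / tht + ith * Nx * Nx; Gi12 <- ith * Nx * Ny; Gi22 <- 1 / tht + ith * Ny * Ny
  Jg <- thp * tht^2

  R <- numeric(pre$n_dof)
  vals <- numeric(n_el * 64)
  for (q in 1:5) {
    g <- pre$gp[[q]]
    volumetric <- q == 5L
    Fc <- f2d_at_gp(u[, 1], u[, 2], el, g$dNdX)
    # Fe (in-plane) = F %*% Gi ; zero elastic out-of-plane strain
    Fe11 <- Fc$F11 * Gi11 + Fc$F12 * Gi12
    Fe12 <- Fc$F11 * Gi12 + Fc$F12 * Gi22
    Fe21 <- Fc$F21 * Gi11 + Fc$F22 * Gi12
    Fe22 <- Fc$F21 * Gi12 + Fc$F22 * Gi22
    dFe <- Fe11 * Fe22 - Fe12 * Fe21
    if (any(!is.finite(dFe)) || any(dFe <= 0)) return(list(bad = TRUE))
    lnJe <- log(dFe)
    # G = Fe^{-T} (in-plane block)
    G11 <- Fe22 / dFe; G12 <- -Fe21 / dFe
    G21 <- -Fe12 / dFe; G22 <- Fe11 / dFe
    # split material law: the isochoric + ground part, mu*(Fe - Fe^-T), is
    # integrated at the 4 gauss points; the volumetric part, L*ln(Je)*Fe^-T,
    # only through the element-mean (B-bar) operator to avoid locking
    if (volumetric) {
      mu1 <- 0; cG <- L * lnJe; dcG <- L
    } else {
      mu1 <- mu; cG <- -mu; dcG <- 0
    }
    Pe11 <- mu1 * Fe11 + cG * G11; Pe12 <- mu1 * Fe12 + cG * G12
    Pe21 <- mu1 * Fe21 + cG * G21; Pe22 <- mu1 * Fe22 + cG * G22
    # P = Jg * Pe %*% Gi^T  (Gi symmetric)
    P11 <- Jg * (Pe11 * Gi11 + Pe12 * Gi12)
    P12 <- Jg * (Pe11 * Gi12 + Pe12 * Gi22)
    P21 <- Jg * (Pe21 * Gi11 + Pe22 * Gi12)
    P22 <- Jg * (Pe21 * Gi12 + Pe22 * Gi22)
    w <- g$wdetJ
    for (a in 1:4) {
      R <- R + scatter_add(pre$n_dof, pre$edof[, 2 * a - 1],
                           (P11 * g$dNdX[, a, 1] + P12 * g$dNdX[, a, 2]) * w)
      R <- R + scatter_add(pre$n_dof, pre$edof[, 2 * a],
                           (P21 * g$dNdX[, a, 1] + P22 * g$dNdX[, a, 2]) * w)
    }
    # material tangent Ae_{imkn} (in-plane indices), then pull back by Gi
    Glist <- list(list(G11, G12), list(G21, G22))
    Ae <- array(list(), c(2, 2, 2, 2))
    for (i in 1:2) for (mm in 1:2) for (kk in 1:2) for (nn2 in 1:2) {
      t1 <- if (i == kk && mm == nn2) mu1 else 0
      t2 <- if (volumetric) dcG * Glist[[kk]][[nn2]] * Glist[[i]][[mm]] else 0
      t3 <- -cG * Glist[[i]][[nn2]] * Glist[[kk]][[mm]]
      Ae[[i, mm, kk, nn2]] <- t1 + t2 + t3
    }
    Gilist <- list(list(Gi11, Gi12), list(Gi12, Gi22))
    A <- array(list(), c(2, 2, 2, 2))
    for (i in 1:2) for (Jd in 1:2) for (kk in 1:2) for (Ld in 1:2) {
      sacc <- 0
      for (mm in 1:2) for (nn2 in 1:2)
        sacc <- sacc + Gilist[[Jd]][[mm]] * Gilist[[Ld]][[nn2]] * Ae[[i, mm, kk, nn2]]
      A[[i, Jd, kk, Ld]] <- Jg * sacc
    }
    idx <- 0L
    for (a in 1:4) for (i in 1:2) for (b in 1:4) for (kk in 1:2) {
      idx <- idx + 1L
      kab <- (g$dNdX[, a, 1] * (A[[i, 1, kk, 1]] * g$dNdX[, b, 1] +
                                A[[i, 1, kk, 2]] * g$dNdX[, b, 2]) +
              g$dNdX[, a, 2] * (A[[i, 2, kk, 1]] * g$dNdX[, b, 1] +
                                A[[i, 2, kk, 2]] * g$dNdX[, b, 2])) * w
      vals[((idx - 1L) * n_el + 1L):(idx * n_el)] <-
        vals[((idx - 1L) * n_el + 1L):(idx * n_el)] + kab
    }
  }
  K <- Matrix::sparseMatrix(i = pre$ii, j = pre$jj, x = vals,
                            dims = c(pre$n_dof, pre$n_dof))
  list(R = R, K = K, bad = FALSE, mu = mu, L = L)
}

solve_equilibrium_2d <- function(mesh, growth, params, u_prev, rtol, max_iter) {
  pre <- mesh$fem_pre
  if (is.null(pre)) pre <- precompute_fem2d(mesh)
  n_el <- nrow(mesh$elements)
  el <- mesh$elements
  thp <- growth$th_par; tht <- growth$th_perp
  stopifnot(length(thp) == n_el, all(thp > 0), all(tht > 0))
  Nx <- mesh$N[, 1]; Ny <- mesh$N[, 2]
  ith <- 1 / thp - 1 / tht
  Gi11 <- 1 / tht + ith * Nx * Nx; Gi12 <- ith * Nx * Ny; Gi22 <- 1 / tht + ith * Ny * Ny
  mu <- L <- NULL

  u <- if (is.null(u_prev)) matrix(0, nrow(mesh$nodes), 2) else u_prev
  fixed <- c(2L * mesh$boundary$symmetry,       # u_y = 0 on the cut edge
             2L * mesh$boundary$pin - 1L)       # pin u_x at the central node
  free <- setdiff(seq_len(pre$n_dof), fixed)
  converged <- FALSE
  f_ref <- max(params$mu_s, 1) * mesh$R0

  for (iter in seq_len(max_iter)) {
    asm <- assemble_2d(mesh, growth, params, u, pre)
    if (asm$bad)
      return(structure(list(u = u, converged = FALSE, iterations = iter),
                       class = "mechanical_state"))
    mu <- asm$mu; L <- asm$L
    R <- asm$R
    f_scale <- max(f_ref, max(abs(R)))
    if (max(abs(R[free])) <= rtol * f_scale) { converged <- TRUE; break }
    du <- tryCatch(Matrix::solve(asm$K[free, free], -R[free]),
                   error = function(e) NULL)
    if (is.null(du))
      return(structure(list(u = u, converged = FALSE, iterations = iter),
                       class = "mechanical_state"))
    unew <- as.vector(t(u)); unew[free] <- unew[free] + as.numeric(du)
    u <- matrix(unew, ncol = 2, byrow = TRUE)
  }
  # per-element state at element center (average of gauss points)
  J <- Je <- numeric(n_el)
  F11a <- F12a <- F21a <- F22a <- numeric(n_el)
  for (q in 1:4) {
    g <- pre$gp[[q]]
    Fc <- f2d_at_gp(u[, 1], u[, 2], el, g$dNdX)
    F11a <- F11a + Fc$F11 / 4; F12a <- F12a + Fc$F12 / 4
    F21a <- F21a + Fc$F21 / 4; F22a <- F22a + Fc$F22 / 4
  }
  detF2 <- F11a * F22a - F12a * F21a
  Fe11 <- F11a * Gi11 + F12a * Gi12; Fe12 <- F11a * Gi12 + F12a * Gi22
  Fe21 <- F21a * Gi11 + F22a * Gi12; Fe22 <- F21a * Gi12 + F22a * Gi22
  dFe <- Fe11 * Fe22 - Fe12 * Fe21
  # total volume ratio includes the freely grown thickness, F33 = th_perp
  structure(list(u = u, converged = converged, iterations = iter,
                 F = list(F11 = F11a, F12 = F12a, F21 = F21a, F22 = F22a),
                 J = detF2 * tht, Je = dFe, growth = growth,
                 mu = mu, L = L),
            class = "mechanical_state")
}
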