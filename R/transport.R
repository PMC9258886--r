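# Per-cohort cell-density balance on the deforming mesh, solved in
# REFERENTIAL form on the fixed reference mesh:
#
#   d(c0_i)/dt = F_i^c + Div Q_i,   c0_i = J c_i,
#   Q_i = J F^-1 q_i,  q_i = -c_i H^((c_i-c0)/c0; a_c) v_i(x) + D grad c_i,
#   F_i^c = J Gc G^x(r) G^t_i(t),
#
# with zero-flux boundaries everywhere. Time stepping is backward Euler;
# the activation nonlinearity is handled by Picard iteration; the advective
# term carries optimal ("exponential-fitting") streamline upwinding, which
# vanishes as the cell Peclet number goes to zero so that diffusion-only
# runs are unpolluted.

#' Spatial neuron flux of one cohort at a material point
#'
#' Advective part \code{-c_i H^ v_hat n/||n||} (migration along the deformed
#' fiber, gated by the density activation) plus Fickian part
#' \code{D grad c_i}.
#'
#' @param c_i Spatial cohort density [1/um^3].
#' @param grad_c_i Spatial density gradient (length 3) [1/um^4].
#' @param F Deformation gradient (3x3).
#' @param N Referential fiber unit vector (length 3).
#' @param r Referential radius [um].
#' @param cohort Cohort index 1..3.
#' @param params \code{cortexfold_params}.
#' @return Spatial flux vector (length 3) [1/(um^2 d)].
#' @export
cohort_flux <- function(c_i, grad_c_i, F, N, r, cohort, params) {
  n <- as.numeric(F %*% N)
  nn <- sqrt(sum(n^2))
  if (nn == 0) stop("degenerate fiber: ||F N|| = 0", call. = FALSE)
  act <- migration_activation(c_i, params)
  vhat <- velocity_magnitude(r, cohort, params)
  -c_i * act * vhat * n / nn + params$D * grad_c_i
}

#' Total cell density across cohorts
#'
#' Pointwise sum of the per-cohort density columns; this is the density that
#' drives the growth tensor.
#'
#' @param fields Matrix (points x cohorts) or vector of densities.
#' @return Numeric vector of total densities.
#' @export
total_density <- function(fields) {
  if (is.matrix(fields)) rowSums(fields) else fields
}

# optimal upwinding factor: coth(Pe) - 1/Pe, -> 0 as Pe -> 0
upwind_xi <- function(pe) {
  out <- numeric(length(pe))
  big <- pe > 1e-4
  out[big] <- 1 / tanh(pe[big]) - 1 / pe[big]
  out[!big] <- pe[!big] / 3
  out
}

# lumped nodal projection of per-element J (bar geometry)
bar_nodal_J <- function(mesh, J_el) {
  h <- diff(mesh$x)
  nn <- length(mesh$x)
  wsum <- numeric(nn); jsum <- numeric(nn)
  wsum[1:(nn - 1)] <- wsum[1:(nn - 1)] + h / 2
  wsum[2:nn] <- wsum[2:nn] + h / 2
  jsum[1:(nn - 1)] <- jsum[1:(nn - 1)] + J_el * h / 2
  jsum[2:nn] <- jsum[2:nn] + J_el * h / 2
  jsum / wsum
}

#' Advance the per-cohort referential densities by one time step
#'
#' Backward-Euler step of the referential density balance on the reference
#' mesh, using the supplied mechanical state for the deformation feedback
#' (volume ratio J and fiber direction n = F N). Negative densities produced
#' by the discrete transport operator are clipped to zero and the clipped
#' mass is reported.
#'
#' @param mesh \code{cortexfold_mesh}.
#' @param c0 Referential densities, matrix n_nodes x n_cohorts.
#' @param mech \code{mechanical_state} from \code{\link{solve_equilibrium}}
#'   (or \code{NULL} for the undeformed state).
#' @param t_new Time at the end of the step [d].
#' @param dt Step size [d].
#' @param params \code{cortexfold_params}.
#' @param n_picard Picard iterations for the activation nonlinearity.
#' @return List with \code{c0} (updated matrix), \code{clipped} (total
#'   clipped referential cell number, per cohort).
#' @export
advance_density <- function(mesh, c0, mech, t_new, dt, params, n_picard = 2) {
  stopifnot(dt > 0)
  switch(mesh$type,
         bar = advance_density_bar(mesh, c0, mech, t_new, dt, params, n_picard),
         halfcircle = advance_density_2d(mesh, c0, mech, t_new, dt, params, n_picard),
         stop("unknown mesh type", call. = FALSE))
}

advance_density_bar <- function(mesh, c0, mech, t_new, dt, params, n_picard) {
  n_el <- mesh$n_elems
  nn <- n_el + 1L
  h <- diff(mesh$x)
  n_coh <- ncol(c0)
  J_el <- if (is.null(mech)) rep(1, n_el) else mech$J
  Fxx <- if (is.null(mech)) rep(1, n_el) else mech$Fxx
  Jn <- bar_nodal_J(mesh, J_el)

  # 2-point Gauss on each element; small dense matrices throughout
  gp <- (1 + c(-1, 1) / sqrt(3)) / 2   # local coords in [0,1]
  Xl <- mesh$x[1:n_el]
  Mi <- matrix(0, nn, nn)
  diag(Mi) <- c(h, 0) / 3 + c(0, h) / 3
  Mi[cbind(1:n_el, 2:nn)] <- h / 6
  Mi[cbind(2:nn, 1:n_el)] <- h / 6
  out_clip <- numeric(n_coh)
  c0_new <- c0
  for (i in seq_len(n_coh)) {
    ci <- c0[, i]
    src <- numeric(nn)
    for (q in 1:2) {
      Xg <- Xl + gp[q] * h
      fsrc <- J_el * params$Gc * neurogenesis_spatial(Xg, params) *
        neurogenesis_temporal(t_new, i, params)
      wq <- h / 2
      src[1:n_el] <- src[1:n_el] + (1 - gp[q]) * fsrc * wq
      src[2:nn] <- src[2:nn] + gp[q] * fsrc * wq
    }
    ck <- ci
    for (pic in seq_len(n_picard)) {
      # assemble S from the flux linearization about the Picard iterate
      SdL <- SdR <- SoLR <- SoRL <- numeric(n_el)  # 2x2 element blocks
      for (q in 1:2) {
        Xg <- Xl + gp[q] * h
        csp_g <- ((1 - gp[q]) * ck[1:n_el] / Jn[1:n_el] +
                  gp[q] * ck[2:nn] / Jn[2:nn])
        act <- migration_activation(pmax(csp_g, 0), params)
        vhat <- velocity_magnitude(Xg, i, params)
        adv <- J_el * act * vhat / Fxx            # coefficient on c (spatial)
        dphys <- J_el * params$D / Fxx^2
        pe <- abs(adv) * h / (2 * pmax(dphys, 1e-300))
        dart <- upwind_xi(pe) * abs(adv) * h / 2
        dtot <- dphys + dart
        wq <- h / 2
        # Q_b = -adv * N_b / Jn_b + dtot * dN_b / Jn_b ; S[a,b] += dN_a * Q_b * wq
        NbL <- (1 - gp[q]) / Jn[1:n_el]; NbR <- gp[q] / Jn[2:nn]
        dNL <- -1 / h / Jn[1:n_el]; dNR <- 1 / h / Jn[2:nn]
        QL <- -adv * NbL + dtot * dNL
        QR <- -adv * NbR + dtot * dNR
        SdL <- SdL + (-1 / h) * QL * wq
        SoLR <- SoLR + (-1 / h) * QR * wq
        SoRL <- SoRL + (1 / h) * QL * wq
        SdR <- SdR + (1 / h) * QR * wq
      }
      A <- Mi / dt
      A[cbind(1:n_el, 1:n_el)] <- A[cbind(1:n_el, 1:n_el)] + SdL
      A[cbind(2:nn, 2:nn)] <- A[cbind(2:nn, 2:nn)] + SdR
      A[cbind(1:n_el, 2:nn)] <- A[cbind(1:n_el, 2:nn)] + SoLR
      A[cbind(2:nn, 1:n_el)] <- A[cbind(2:nn, 1:n_el)] + SoRL
      b <- as.numeric(Mi %*% ci) / dt + src
      ck <- solve(A, b)
    }
    neg <- ck < 0
    if (any(neg)) {
      lump <- rowSums(Mi)
      out_clip[i] <- out_clip[i] + sum(-ck[neg] * lump[neg])
      ck[neg] <- 0
    }
    c0_new[, i] <- ck
  }
  list(c0 = c0_new, clipped = out_clip)
}

# nodal projection of per-gauss-point J over a half-circle mesh
nodal_project <- function(mesh, pre, J_gp) {
  nn <- nrow(mesh$nodes)
  num <- numeric(nn); den <- numeric(nn)
  for (q in 1:4) {
    g <- pre$gp[[q]]
    for (a in 1:4) {
      idx <- mesh$elements[, a]
      w <- g$Nsh[a] * g$wdetJ
      num <- num + scatter_add(nn, idx, w * J_gp[[q]])
      den <- den + scatter_add(nn, idx, w)
    }
  }
  num / den
}

advance_density_2d <- function(mesh, c0, mech, t_new, dt, params, n_picard) {
  pre <- mesh$fem_pre
  if (is.null(pre)) pre <- precompute_fem2d(mesh)
  el <- mesh$elements
  n_el <- nrow(el)
  nn <- nrow(mesh$nodes)
  n_coh <- ncol(c0)
  ux <- if (is.null(mech)) numeric(nn) else mech$u[, 1]
  uy <- if (is.null(mech)) numeric(nn) else mech$u[, 2]

  # deformation per gauss point; total volume ratio includes the grown
  # thickness F33 = th_perp (zero elastic out-of-plane strain)
  tht_el <- if (is.null(mech)) rep(1, n_el) else mech$growth$th_perp
  Fgp <- lapply(1:4, function(q) f2d_at_gp(ux, uy, el, pre$gp[[q]]$dNdX))
  Jgp <- lapply(Fgp, function(Fc) (Fc$F11 * Fc$F22 - Fc$F12 * Fc$F21) * tht_el)
  Jn <- nodal_project(mesh, pre, Jgp)

  Nx <- mesh$N[, 1]; Ny <- mesh$N[, 2]
  Mtrip <- mass_matrix_2d(mesh, pre)
  out_clip <- numeric(n_coh)
  c0_new <- c0
  for (i in seq_len(n_coh)) {
    ci <- c0[, i]
    src <- numeric(nn)
    for (q in 1:4) {
      g <- pre$gp[[q]]
      fsrc <- Jgp[[q]] * params$Gc * neurogenesis_spatial(g$r, params) *
        neurogenesis_temporal(t_new, i, params)
      for (a in 1:4)
        src <- src + scatter_add(nn, el[, a], g$Nsh[a] * fsrc * g$wdetJ)
    }
    ck <- ci
    for (pic in seq_len(n_picard)) {
      vals <- numeric(n_el * 16)
      for (q in 1:4) {
        g <- pre$gp[[q]]
        Fc <- Fgp[[q]]; Jq <- Jgp[[q]]
        det2 <- Jq / tht_el
        # in-plane F^{-1}: [F22 -F12; -F21 F11]/det2
        Fi11 <- Fc$F22 / det2; Fi12 <- -Fc$F12 / det2
        Fi21 <- -Fc$F21 / det2; Fi22 <- Fc$F11 / det2
        # deformed fiber direction n = F N
        nx <- Fc$F11 * Nx + Fc$F12 * Ny
        ny <- Fc$F21 * Nx + Fc$F22 * Ny
        nrm <- sqrt(nx^2 + ny^2)
        nx <- nx / nrm; ny <- ny / nrm
        csp <- numeric(n_el)
        for (a in 1:4) csp <- csp + g$Nsh[a] * ck[el[, a]] / Jn[el[, a]]
        act <- migration_activation(pmax(csp, 0), params)
        vhat <- velocity_magnitude(g$r, i, params)
        # referential advection vector a_ref = J F^-1 (act*vhat*n)
        ax <- Jq * (Fi11 * (act * vhat * nx) + Fi12 * (act * vhat * ny))
        ay <- Jq * (Fi21 * (act * vhat * nx) + Fi22 * (act * vhat * ny))
        # referential diffusion tensor Dref = J D F^-1 F^-T
        d11 <- Jq * params$D * (Fi11^2 + Fi12^2)
        d12 <- Jq * params$D * (Fi11 * Fi21 + Fi12 * Fi22)
        d22 <- Jq * params$D * (Fi21^2 + Fi22^2)
        amag <- sqrt(ax^2 + ay^2)
        ahx <- ifelse(amag > 0, ax / amag, 0)
        ahy <- ifelse(amag > 0, ay / amag, 0)
        da <- pmax(d11 * ahx^2 + 2 * d12 * ahx * ahy + d22 * ahy^2, 1e-300)
        he <- sqrt(4 * g$wdetJ)
        pe <- amag * he / (2 * da)
        kart <- upwind_xi(pe) * amag * he / 2
        k11 <- d11 + kart * ahx * ahx
        k12 <- d12 + kart * ahx * ahy
        k22 <- d22 + kart * ahy * ahy
        w <- g$wdetJ
        idx <- 0L
        for (a in 1:4) for (b in 1:4) {
          idx <- idx + 1L
          iJb <- 1 / Jn[el[, b]]
          qx <- (-ax * g$Nsh[b] + k11 * g$dNdX[, b, 1] + k12 * g$dNdX[, b, 2]) * iJb
          qy <- (-ay * g$Nsh[b] + k12 * g$dNdX[, b, 1] + k22 * g$dNdX[, b, 2]) * iJb
          sab <- (g$dNdX[, a, 1] * qx + g$dNdX[, a, 2] * qy) * w
          vals[((idx - 1L) * n_el + 1L):(idx * n_el)] <-
            vals[((idx - 1L) * n_el + 1L):(idx * n_el)] + sab
        }
      }
      S <- Matrix::sparseMatrix(i = Mtrip$ii, j = Mtrip$jj, x = vals,
                                dims = c(nn, nn))
      A <- Mtrip$M / dt + S
      b <- as.numeric(Mtrip$M %*% ci) / dt + src
      ck <- tryCatch(as.numeric(Matrix::solve(A, b)),
                     error = function(e) stop("transport linear solve failed",
                                              call. = FALSE))
    }
    neg <- ck < 0
    if (any(neg)) {
      out_clip[i] <- out_clip[i] + sum(-ck[neg] * Mtrip$lump[neg])
      ck[neg] <- 0
    }
    c0_new[, i] <- ck
  }
  list(c0 = c0_new, clipped = out_clip)
}

mesh_h <- function(pre) {
  # characteristic element size^2: total element area via gauss weights
  area <- 0
  for (q in 1:4) area <- area + pre$gp[[q]]$wdetJ
  area
}

mass_matrix_2d <- function(mesh, pre) {
  el <- mesh$elements
  n_el <- nrow(el)
  nn <- nrow(mesh$nodes)
  ii <- matrix(0L, n_el, 16); jj <- matrix(0L, n_el, 16)
  k <- 0L
  for (a in 1:4) for (b in 1:4) {
    k <- k + 1L
    ii[, k] <- el[, a]; jj[, k] <- el[, b]
  }
  vals <- numeric(n_el * 16)
  for (q in 1:4) {
    g <- pre$gp[[q]]
    idx <- 0L
    for (a in 1:4) for (b in 1:4) {
      idx <- idx + 1L
      vals[((idx - 1L) * n_el + 1L):(idx * n_el)] <-
        vals[((idx - 1L) * n_el + 1L):(idx * n_el)] +
        g$Nsh[a] * g$Nsh[b] * g$wdetJ
    }
  }
  M <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj), x = vals,
                            dims = c(nn, nn))
  list(M = M, ii = as.vector(ii), jj = as.vector(jj),
       lump = as.numeric(M %*% rep(1, nn)))
}
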