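# Pointwise kinematics of growth and elasticity.
#
# The total deformation gradient factors multiplicatively, F = Fe %*% Fg:
# Fg is the stress-free shape change driven by the local cell density, Fe
# the elastic accommodation that generates stress. Tensors are kept as full
# 3x3 matrices even in reduced-dimension runs so that densities stay
# per-unit-volume.

#' Growth tensor from total cell density
#'
#' Transversely isotropic growth about the fiber direction \code{N}:
#' stretch \code{1 + k_par*c} along the fiber and \code{1 + k_perp*c} in the
#' plane orthogonal to it, where \code{c} is the total (summed over cohorts)
#' spatial cell density.
#'
#' @param c_total Total spatial cell density [1/um^3].
#' @param k_par Fiber-parallel growth coefficient [um^3].
#' @param k_perp Fiber-perpendicular growth coefficient [um^3].
#' @param N Referential fiber unit vector (length 3).
#' @return 3x3 growth tensor.
#' @export
growth_tensor <- function(c_total, k_par, k_perp, N) {
  stopifnot(length(N) == 3L, c_total >= 0)
  nn <- sum(N * N)
  if (abs(nn - 1) > 1e-8) stop("'N' must be a unit vector", call. = FALSE)
  th_par <- 1 + k_par * c_total
  th_perp <- 1 + k_perp * c_total
  if (th_par <= 0 || th_perp <= 0)
    stop("degenerate growth: 1 + k*c must stay positive", call. = FALSE)
  NN <- tcrossprod(N)
  th_par * NN + th_perp * (diag(3) - NN)
}

#' Elastic decomposition of a deformation state
#'
#' Given total \code{F} and growth \code{Fg}, computes
#' \code{Fe = F Fg^-1}, the determinants \code{J}, \code{Je}, \code{Jg}
#' (satisfying \code{J = Je*Jg}), and the elastic left/right Cauchy-Green
#' tensors \code{Be = Fe Fe^T}, \code{Ce = Fe^T Fe}.
#'
#' @param F Total deformation gradient (3x3, det > 0).
#' @param Fg Growth tensor (3x3, det > 0).
#' @return A list of class \code{deformation_state} with fields \code{F},
#'   \code{Fg}, \code{Fe}, \code{J}, \code{Je}, \code{Jg}, \code{Be},
#'   \code{Ce}.
#' @export
elastic_decomposition <- function(F, Fg) {
  J <- det(F)
  Jg <- det(Fg)
  if (!is.finite(J) || J <= 0) stop("det(F) must be positive", call. = FALSE)
  if (!is.finite(Jg) || Jg <= 0) stop("'Fg' must be non-singular with positive determinant", call. = FALSE)
  Fe <- F %*% solve(Fg)
  structure(list(F = F, Fg = Fg, Fe = Fe,
                 J = J, Jg = Jg, Je = det(Fe),
                 Be = tcrossprod(Fe), Ce = crossprod(Fe)),
            class = "deformation_state")
}

#' Neo-Hookean referential free energy density
#'
#' \code{psi = mu/2 * (tr(Ce) - 3 - 2 ln Je) + L/2 * ln(Je)^2}: zero in the
#' elastically undeformed state, penalizing both isochoric distortion and
#' elastic volume change.
#'
#' @param Ce Elastic right Cauchy-Green tensor (3x3 SPD).
#' @param Je Elastic volume ratio (> 0).
#' @param mu Shear modulus [kPa].
#' @param L Second Lame constant [kPa].
#' @return Energy density [kPa].
#' @export
strain_energy <- function(Ce, Je, mu, L) {
  if (Je <= 0) stop("'Je' must be positive", call. = FALSE)
  mu / 2 * (sum(diag(Ce)) - 3 - 2 * log(Je)) + L / 2 * log(Je)^2
}

#' Cauchy stress of the neo-Hookean model
#'
#' \code{T = (1/Je) * (mu * Be + (L ln(Je) - mu) * I)}; symmetric, and zero
#' when \code{Fe} is the identity (only elastic deformation induces stress).
#'
#' @param Fe Elastic deformation gradient (3x3, det > 0).
#' @param mu Shear modulus [kPa].
#' @param L Second Lame constant [kPa].
#' @return 3x3 symmetric Cauchy stress [kPa].
#' @export
cauchy_stress <- function(Fe, mu, L) {
  Je <- det(Fe)
  if (!is.finite(Je) || Je <= 0) stop("det(Fe) must be positive", call. = FALSE)
  Be <- tcrossprod(Fe)
  (mu * Be + (L * log(Je) - mu) * diag(3)) / Je
}

# First Piola-Kirchhoff stress wrt Fe: Pe = mu*Fe + (L ln Je - mu) * Fe^-T.
# Internal workhorse of the FEM residual.
pk1_elastic <- function(Fe, mu, L) {
  Je <- det(Fe)
  G <- t(solve(Fe))
  mu * Fe + (L * log(Je) - mu) * G
}
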