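# Model constants and the smooth spatial/temporal parameter profiles.
#
# All spatial profiles are functions of the REFERENTIAL radial coordinate
# r = ||x_R|| (for the bar geometry, the axial material coordinate).
# Smoothing parameters alpha_G, alpha_v, alpha_k, alpha_mu carry units 1/um;
# alpha_c is dimensionless and acts on the normalized density (c - c0)/c0.

#' Model parameters for the coupled migration--growth model
#'
#' Construct the full parameter set of the model: the threshold and
#' sensitivity of migration activation, geometry, neurogenesis profile
#' constants, per-cohort electroporation times and destinations, growth and
#' stiffness profiles, elastic moduli, and the calibratable transport/growth
#' constants. Defaults are the predefined and calibrated values for the
#' developing ferret cortex.
#'
#' @param c0 Threshold cell density for migration activation [1/um^3].
#' @param alpha_c Activation sensitivity (dimensionless; applied to the
#'   normalized excess density \code{(c - c0)/c0}).
#' @param R0 Initial radius / bar length [um].
#' @param delta_x Extent of the ventricular (neurogenic) zone [um].
#' @param alpha_G Neurogenesis spatial smoothing [1/um].
#' @param delta_it Per-cohort electroporation (birth) times, length 3 [d].
#' @param epsilon Temporal smoothing of the neurogenesis pulse [d].
#' @param alpha_v Velocity-profile smoothing [1/um].
#' @param beta_k Tangential/radial growth ratio in the cortex [-].
#' @param delta_k Radius of the growth-mode transition [um].
#' @param alpha_k Growth-profile smoothing [1/um].
#' @param mu_s Subcortical shear modulus [kPa].
#' @param nu Poisson ratio (spatially uniform) [-].
#' @param L_s Subcortical second Lame constant [kPa].
#' @param beta_mu Cortex/subcortex stiffness ratio [-].
#' @param delta_mu Radius of the stiffness transition [um].
#' @param alpha_mu Stiffness-profile smoothing [1/um].
#' @param Gc Baseline division-rate constant [1/(um^3 d)].
#' @param v_base Baseline migration velocity constant, shared by cohorts
#'   [um/d].
#' @param delta_iv Per-cohort final destinations, length 3, strictly
#'   increasing [um].
#' @param D Diffusion coefficient [um^2/d].
#' @param k_s Subcortical growth parameter [um^3].
#' @param tau Total simulated duration [d].
#'
#' @return An object of class \code{cortexfold_params} (a validated list).
#' @examples
#' p <- model_parameters()
#' p$R0
#' shear_modulus(0, p)          # subcortical plateau, ~1 kPa
#' shear_modulus(p$R0, p)       # cortical plateau, ~3 kPa
#' @export
model_parameters <- function(c0 = 1.0e-6,
                             alpha_c = 0.1,
                             R0 = 239.0,
                             delta_x = 0.2 * 239.0,
                             alpha_G = 0.05,
                             delta_it = c(0, 3, 6),
                             epsilon = 2.0,
                             alpha_v = 0.05,
                             beta_k = 1.0,
                             delta_k = 0.93 * 239.0,
                             alpha_k = 1.0,
                             mu_s = 1.0,
                             nu = 0.45,
                             L_s = 9.3,
                             beta_mu = 3.0,
                             delta_mu = 0.93 * 239.0,
                             alpha_mu = 1.0,
                             Gc = 1.41e-5,
                             v_base = 1472.2,
                             delta_iv = c(191.6, 210.7, 222.7),
                             D = 31612.6,
                             k_s = 202950,
                             tau = 27.0) {
  p <- list(c0 = c0, alpha_c = alpha_c, R0 = R0, delta_x = delta_x,
            alpha_G = alpha_G, delta_it = delta_it, epsilon = epsilon,
            alpha_v = alpha_v, beta_k = beta_k, delta_k = delta_k,
            alpha_k = alpha_k, mu_s = mu_s, nu = nu, L_s = L_s,
            beta_mu = beta_mu, delta_mu = delta_mu, alpha_mu = alpha_mu,
            Gc = Gc, v_base = v_base, delta_iv = delta_iv, D = D,
            k_s = k_s, tau = tau)
  validate_parameters(p)
}

validate_parameters <- function(p) {
  stopifnot(is.list(p))
  num_pos <- c("c0", "alpha_c", "R0", "delta_x", "alpha_G", "epsilon",
               "alpha_v", "delta_k", "alpha_k", "mu_s", "L_s", "delta_mu",
               "alpha_mu", "k_s", "tau")
  for (k in num_pos) {
    if (!is.numeric(p[[k]]) || length(p[[k]]) != 1L || !is.finite(p[[k]]) ||
        p[[k]] <= 0) {
      stop("parameter '", k, "' must be a single positive number", call. = FALSE)
    }
  }
  for (k in c("Gc", "v_base", "D")) {   # rates: zero is a legitimate degenerate
    if (!is.numeric(p[[k]]) || length(p[[k]]) != 1L || !is.finite(p[[k]]) ||
        p[[k]] < 0)
      stop("parameter '", k, "' must be a single nonnegative number", call. = FALSE)
  }
  if (length(p$delta_it) != 3L || is.unsorted(p$delta_it) || any(p$delta_it < 0))
    stop("'delta_it' must be 3 nondecreasing nonnegative times", call. = FALSE)
  if (length(p$delta_iv) != 3L || any(diff(p$delta_iv) <= 0) || any(p$delta_iv <= 0))
    stop("'delta_iv' must be 3 strictly increasing positive radii", call. = FALSE)
  if (p$nu <= 0 || p$nu >= 0.5)
    stop("'nu' must lie in (0, 0.5)", call. = FALSE)
  if (p$beta_mu < 1) stop("'beta_mu' must be >= 1", call. = FALSE)
  if (p$beta_k < 1) stop("'beta_k' must be >= 1", call. = FALSE)
  structure(p, class = "cortexfold_params")
}

#' @export
print.cortexfold_params <- function(x, ...) {
  cat("<cortexfold model parameters>\n")
  cat(sprintf("  domain: R0 = %.1f um, tau = %g d, cohorts born at [%s] d\n",
              x$R0, x$tau, paste(x$delta_it, collapse = ", ")))
  cat(sprintf("  growth: k_s = %g um^3, beta_k = %g; stiffness: mu_s = %g kPa, beta_mu = %g\n",
              x$k_s, x$beta_k, x$mu_s, x$beta_mu))
  cat(sprintf("  transport: Gc = %g /um^3/d, v = %g um/d, D = %g um^2/d\n",
              x$Gc, x$v_base, x$D))
  cat(sprintf("  destinations delta_iv = [%s] um\n",
              paste(x$delta_iv, collapse = ", ")))
  invisible(x)
}

#' Read / write model parameters as a YAML configuration file
#'
#' The configuration keys are the argument names of
#' \code{\link{model_parameters}} (units as documented there). Unknown keys
#' are an error so that typos cannot silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return \code{read_parameters} returns a validated
#'   \code{cortexfold_params}; \code{write_parameters} returns \code{path}
#'   invisibly.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- names(formals(model_parameters))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(model_parameters, cfg)
}

#' @rdname read_parameters
#' @param params A \code{cortexfold_params} object.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "cortexfold_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' Smoothed Heaviside (logistic) transition function
#'
#' \code{exp(alpha * x) / (1 + exp(alpha * x))}: strictly increasing in
#' \code{x}, 0.5 at \code{x = 0}, with saturation limits 0 and 1. This single
#' primitive generates every smooth spatial transition of the model
#' (activation, neurogenic zone, velocity, growth-mode and stiffness
#' profiles).
#'
#' @param x Argument (any real, vectorized).
#' @param alpha Positive steepness; the transition width is ~\code{1/alpha}
#'   in the units of \code{x}.
#' @return Values in (0, 1).
#' @export
smoothed_heaviside <- function(x, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("'alpha' must be a single positive number", call. = FALSE)
  stats::plogis(alpha * x)
}

#' Migration activation as a function of cohort density
#'
#' Migration of a cohort switches on smoothly once its density exceeds the
#' threshold \code{c0}; it is halfway activated at \code{c = c0}. The
#' logistic acts on the normalized excess density \code{(c - c0)/c0} with
#' sensitivity \code{alpha_c}.
#'
#' @param c_i Spatial cohort density [1/um^3] (vectorized).
#' @param params \code{cortexfold_params}.
#' @return Activation in (0, 1).
#' @export
migration_activation <- function(c_i, params) {
  smoothed_heaviside((c_i - params$c0) / params$c0, params$alpha_c)
}

#' Spatial neurogenesis profile
#'
#' ~1 inside the ventricular zone (r < delta_x), decaying smoothly to ~0
#' outside, with transition width ~1/alpha_G.
#'
#' @param r Referential radius [um] (vectorized).
#' @param params \code{cortexfold_params}.
#' @export
neurogenesis_spatial <- function(r, params) {
  smoothed_heaviside(params$delta_x - r, params$alpha_G)
}

#' Temporal neurogenesis pulse for one cohort
#'
#' Cauchy-type bump \code{eps^2 / ((t - delta_it)^2 + eps^2)} peaking at 1
#' when \code{t} equals the cohort's electroporation time, with half-width
#' \code{epsilon}.
#'
#' @param t Time [d] (vectorized).
#' @param cohort Cohort index in 1..3.
#' @param params \code{cortexfold_params}.
#' @export
neurogenesis_temporal <- function(t, cohort, params) {
  stopifnot(cohort %in% seq_along(params$delta_it))
  e2 <- params$epsilon^2
  e2 / ((t - params$delta_it[cohort])^2 + e2)
}

#' Signed migration velocity magnitude along the fiber direction
#'
#' \code{v_base * H^(delta_iv - r; alpha_v) - 0.5 * v_base}: approximately
#' +v_base/2 well inside the destination radius, exactly zero at
#' \code{r = delta_iv[cohort]}, and approximately -v_base/2 beyond it, so
#' cells are advected toward the cohort's destination from both sides and
#' migration ceases there.
#'
#' @param r Referential radius [um] (vectorized).
#' @param cohort Cohort index in 1..3.
#' @param params \code{cortexfold_params}.
#' @return Signed speed [um/d].
#' @export
velocity_magnitude <- function(r, cohort, params) {
  stopifnot(cohort %in% seq_along(params$delta_iv))
  params$v_base *
    (smoothed_heaviside(params$delta_iv[cohort] - r, params$alpha_v) - 0.5)
}

#' Radial profiles of the growth coefficients
#'
#' In the subcortex (r << delta_k) both coefficients equal \code{k_s}; in the
#' cortex the fiber-parallel (radial) coefficient drops to \code{k_s/beta_k}
#' while the fiber-perpendicular (tangential) coefficient rises to
#' \code{k_s*beta_k}, so tangential growth dominates where neurons settle.
#'
#' @param r Referential radius [um] (vectorized).
#' @param params \code{cortexfold_params}.
#' @return List with components \code{k_par} and \code{k_perp} [um^3].
#' @export
growth_coefficients <- function(r, params) {
  H <- smoothed_heaviside(r - params$delta_k, params$alpha_k)
  list(k_par  = params$k_s + params$k_s * (1 / params$beta_k - 1) * H,
       k_perp = params$k_s + params$k_s * (params$beta_k - 1) * H)
}

#' Radial profile of the shear modulus
#'
#' \code{mu_s} in the subcortex rising smoothly to \code{beta_mu * mu_s} in
#' the cortex across radius \code{delta_mu}.
#'
#' @param r Referential radius [um] (vectorized).
#' @param params \code{cortexfold_params}.
#' @return Shear modulus [kPa].
#' @export
shear_modulus <- function(r, params) {
  params$mu_s +
    params$mu_s * (params$beta_mu - 1) *
      smoothed_heaviside(r - params$delta_mu, params$alpha_mu)
}

#' Radial profile of the second Lame constant
#'
#' Scales with the shear-modulus profile, \code{L(r) = L_s * mu(r)/mu_s},
#' i.e. the Poisson ratio is spatially uniform.
#'
#' @param r Referential radius [um] (vectorized).
#' @param params \code{cortexfold_params}.
#' @return Second Lame constant [kPa].
#' @export
lame_L <- function(r, params) {
  params$L_s * shear_modulus(r, params) / params$mu_s
}
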