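# Staggered growth--transport--equilibrium time loop: each step advances the
# three cohort densities on the deforming mesh, updates the growth tensor
# from the total spatial density, and re-solves mechanical equilibrium.
# Mechanics substeps (growth-increment halving) absorb occasional Newton
# failures near the buckling point.

#' Simulation configuration
#'
#' @param params \code{cortexfold_params} (defaults to
#'   \code{model_parameters()}).
#' @param geometry \code{"bar"} (calibration geometry) or
#'   \code{"halfcircle"} (folding geometry).
#' @param n_elems Bar element count.
#' @param target_elems Half-circle element count target.
#' @param dt Time step [d]; must divide the output cadence.
#' @param k_perp_zero If \code{TRUE} (bar default) tangential growth is
#'   switched off, so the bar grows only axially.
#' @param output_every Output cadence [d].
#' @param timepoints Simulation times of the three experimental imaging
#'   timepoints [d].
#' @param perturb_amp Radial surface perturbation amplitude for the
#'   half-circle [um]; defaults to \code{1e-3 * R0} there and 0 for the bar.
#' @param perturb_seed Seed of the deterministic surface perturbation.
#' @param stop_after_onset If positive, a half-circle run is terminated this
#'   many days after folding onset is first detected (saves time in sweeps).
#' @param onset_threshold Surface-deviation threshold for onset, as a
#'   fraction of R0.
#' @param n_cohorts Number of simulated cohorts (3, or 1 for the reduced
#'   single-cohort model).
#' @return List of class \code{cortexfold_config}.
#' @export
simulation_config <- function(params = model_parameters(),
                              geometry = c("bar", "halfcircle"),
                              n_elems = 60,
                              target_elems = 1147,
                              dt = 0.05,
                              k_perp_zero = NULL,
                              output_every = 0.5,
                              timepoints = c(8.5, 16.5, 27),
                              perturb_amp = NULL,
                              perturb_seed = 20339L,
                              stop_after_onset = 0,
                              onset_threshold = 0.01,
                              n_cohorts = 3L) {
  geometry <- match.arg(geometry)
  stopifnot(inherits(params, "cortexfold_params"), dt > 0)
  if (is.null(k_perp_zero)) k_perp_zero <- geometry == "bar"
  if (is.null(perturb_amp))
    perturb_amp <- if (geometry == "halfcircle") 1e-3 * params$R0 else 0
  stopifnot(n_cohorts %in% c(1L, 3L))
  tp <- sort(timepoints)
  stopifnot(length(tp) == 3, tp[1] > 0, tp[3] <= params$tau)
  chk <- c(output_every, tp)
  if (any(abs(chk / dt - round(chk / dt)) > 1e-9))
    stop("'dt' must divide the output cadence and the timepoints", call. = FALSE)
  structure(list(params = params, geometry = geometry, n_elems = n_elems,
                 target_elems = target_elems, dt = dt,
                 k_perp_zero = k_perp_zero, output_every = output_every,
                 timepoints = tp, perturb_amp = perturb_amp,
                 perturb_seed = perturb_seed,
                 stop_after_onset = stop_after_onset,
                 onset_threshold = onset_threshold,
                 n_cohorts = as.integer(n_cohorts)),
            class = "cortexfold_config")
}

# Growth stretches per element from nodal referential densities. The
# spatial density in the growth law is the referential density diluted by
# the growth volume, c = c0/Jg, with Jg = th_par * th_perp^2; the coupled
# algebraic system is solved pointwise by fixed-point iteration. Excluding
# the (near-unity) elastic volume change from this dilution keeps the
# staggered growth--mechanics coupling stable.
growth_from_density <- function(mesh, c0, J_el, params, k_perp_zero) {
  ctot <- total_density(c0)
  if (mesh$type == "bar") {
    c0_mid <- (ctot[-length(ctot)] + ctot[-1]) / 2
    r <- bar_midpoints(mesh)
  } else {
    el <- mesh$elements
    c0_mid <- (ctot[el[, 1]] + ctot[el[, 2]] + ctot[el[, 3]] + ctot[el[, 4]]) / 4
    cent <- (mesh$nodes[el[, 1], ] + mesh$nodes[el[, 2], ] +
             mesh$nodes[el[, 3], ] + mesh$nodes[el[, 4], ]) / 4
    r <- sqrt(rowSums(cent^2))
  }
  c0_mid <- pmax(c0_mid, 0)
  k <- growth_coefficients(r, params)
  kpar <- k$k_par
  kperp <- if (k_perp_zero) numeric(length(kpar)) else k$k_perp
  thp <- rep(1, length(c0_mid)); tht <- rep(1, length(c0_mid))
  for (it in 1:60) {
    Jg <- thp * tht^2
    thp_new <- 1 + kpar * c0_mid / Jg
    tht_new <- 1 + kperp * c0_mid / Jg
    # damped update for robustness at large k*c0
    thp_new <- 0.5 * (thp + thp_new); tht_new <- 0.5 * (tht + tht_new)
    if (max(abs(thp_new - thp), abs(tht_new - tht)) < 1e-12 * max(1, max(thp)))
      { thp <- thp_new; tht <- tht_new; break }
    thp <- thp_new; tht <- tht_new
  }
  list(th_par = thp, th_perp = tht)
}

# mechanics solve with growth-increment substepping on Newton failure
solve_mech_substep <- function(mesh, g_old, g_new, params, u_prev,
                               max_halvings = 5) {
  n_sub <- 1L
  repeat {
    u <- u_prev
    mech <- NULL
    ok <- TRUE
    for (s in seq_len(n_sub)) {
      lam <- s / n_sub
      g <- list(th_par = (1 - lam) * g_old$th_par + lam * g_new$th_par,
                th_perp = (1 - lam) * g_old$th_perp + lam * g_new$th_perp)
      mech <- solve_equilibrium(mesh, g, params, u_prev = u)
      if (!mech$converged) { ok <- FALSE; break }
      u <- mech$u
    }
    if (ok) return(mech)
    n_sub <- n_sub * 2L
    if (n_sub > 2^max_halvings)
      stop("mechanics failed to converge after growth-step halving", call. = FALSE)
  }
}

frame_from_state <- function(mesh, mech, c0, t, params) {
  if (mesh$type == "bar") {
    Jn <- bar_nodal_J(mesh, if (is.null(mech)) rep(1, mesh$n_elems) else mech$J)
    c_sp <- c0 / Jn
    Fxx <- if (is.null(mech)) rep(1, mesh$n_elems) else mech$Fxx
    u <- if (is.null(mech)) numeric(length(mesh$x)) else mech$u
    list(t = t, geometry = "bar", u = u, c0 = c0, c_spatial = c_sp,
         J = Fxx, length = mesh$R0 + u[length(u)],
         ln_lambda = log(pmax(Fxx, 1)),
         fiber = cbind(Fxx, 0, 0))
  } else {
    pre <- mesh$fem_pre
    if (is.null(pre)) pre <- precompute_fem2d(mesh)
    nn <- nrow(mesh$nodes)
    if (is.null(mech)) {
      u <- matrix(0, nn, 2)
      Jn <- rep(1, nn)
      Fl <- list(F11 = rep(1, mesh$n_elems), F12 = numeric(mesh$n_elems),
                 F21 = numeric(mesh$n_elems), F22 = rep(1, mesh$n_elems))
      J_el <- rep(1, mesh$n_elems)
    } else {
      u <- mech$u
      tht_el <- mech$growth$th_perp
      Fgp <- lapply(1:4, function(q) f2d_at_gp(u[, 1], u[, 2],
                                               mesh$elements, pre$gp[[q]]$dNdX))
      Jgp <- lapply(Fgp, function(Fc) (Fc$F11 * Fc$F22 - Fc$F12 * Fc$F21) * tht_el)
      Jn <- nodal_project(mesh, pre, Jgp)
      Fl <- mech$F
      J_el <- mech$J
    }
    c_sp <- c0 / Jn
    # largest principal stretch of F (F33 = 1)
    C11 <- Fl$F11^2 + Fl$F21^2
    C12 <- Fl$F11 * Fl$F12 + Fl$F21 * Fl$F22
    C22 <- Fl$F12^2 + Fl$F22^2
    tr2 <- (C11 + C22) / 2
    disc <- sqrt(pmax(tr2^2 - (C11 * C22 - C12^2), 0))
    lam <- sqrt(pmax(tr2 + disc, 1))
    nx <- Fl$F11 * mesh$N[, 1] + Fl$F12 * mesh$N[, 2]
    ny <- Fl$F21 * mesh$N[, 1] + Fl$F22 * mesh$N[, 2]
    surf <- mesh$boundary$surface
    list(t = t, geometry = "halfcircle", u = u, c0 = c0, c_spatial = c_sp,
         J = J_el, ln_lambda = log(lam),
         fiber = cbind(nx, ny, 0),
         surface = cbind(x = mesh$nodes[surf, 1] + u[surf, 1],
                         y = mesh$nodes[surf, 2] + u[surf, 2]),
         surface_theta = mesh$boundary$surface_theta)
  }
}

#' Run the coupled growth--transport--equilibrium simulation
#'
#' Advances the model from a stress-free, neuron-free state at day 0 to
#' \code{params$tau}, with three cohorts of neurons seeded by the temporal
#' neurogenesis pulses, and returns output frames at the configured cadence
#' (plus exactly at the three experimental timepoints). Deterministic given
#' the configuration.
#'
#' @param config A \code{cortexfold_config} from
#'   \code{\link{simulation_config}}.
#' @param verbose Print progress lines.
#' @return List of class \code{cortexfold_sim} with \code{frames},
#'   \code{mesh}, \code{config}, \code{clipped} (cumulative clipped cell
#'   number per cohort) and \code{steps} (acceptance log).
#' @export
run_simulation <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "cortexfold_config"))
  p <- config$params
  mesh <- if (config$geometry == "bar") {
    make_bar_mesh(p$R0, config$n_elems)
  } else {
    m <- make_halfcircle_mesh(p$R0, config$target_elems,
                              perturb_amp = config$perturb_amp,
                              perturb_seed = config$perturb_seed)
    m$fem_pre <- precompute_fem2d(m)
    m
  }
  nn <- if (mesh$type == "bar") length(mesh$x) else nrow(mesh$nodes)
  n_el <- mesh$n_elems
  n_coh <- if (is.null(config$n_cohorts)) 3L else config$n_cohorts
  c0 <- matrix(0, nn, n_coh)
  mech <- NULL
  g_old <- list(th_par = rep(1, n_el), th_perp = rep(1, n_el))
  dt <- config$dt
  n_steps <- as.integer(round(p$tau / dt))
  out_times <- sort(unique(c(seq(config$output_every, p$tau, by = config$output_every),
                             config$timepoints)))
  frames <- list(frame_from_state(mesh, mech, c0, 0, p))
  clipped <- numeric(n_coh)
  steps <- data.frame(t = numeric(0), newton_iters = integer(0))
  onset_at <- NA_real_
  J_el <- rep(1, n_el)

  for (s in seq_len(n_steps)) {
    t_new <- s * dt
    tr <- advance_density(mesh, c0, mech, t_new, dt, p)
    c0 <- tr$c0
    clipped <- clipped + tr$clipped
    g_new <- growth_from_density(mesh, c0, J_el, p, config$k_perp_zero)
    mech <- solve_mech_substep(mesh, g_old, g_new, p,
                               if (is.null(mech)) NULL else mech$u)
    J_el <- mech$J
    g_old <- g_new
    steps <- rbind(steps, data.frame(t = t_new, newton_iters = mech$iterations))
    if (any(abs(out_times - t_new) < 1e-9)) {
      fr <- frame_from_state(mesh, mech, c0, t_new, p)
      frames[[length(frames) + 1L]] <- fr
      if (verbose)
        message(sprintf("t = %5.2f d  (%s)", t_new,
                        if (mesh$type == "bar")
                          sprintf("length %.1f um", fr$length)
                        else sprintf("J range %.2f-%.2f", min(fr$J), max(fr$J))))
      if (mesh$type == "halfcircle" && config$stop_after_onset > 0 &&
          is.na(onset_at)) {
        dev <- surface_deviation(fr)
        if (is.finite(dev) && dev > config$onset_threshold * p$R0)
          onset_at <- t_new
      }
      if (!is.na(onset_at) && t_new >= onset_at + config$stop_after_onset)
        break
    }
  }
  structure(list(frames = frames, mesh = mesh, config = config,
                 clipped = clipped, steps = steps),
            class = "cortexfold_sim")
}

#' @export
print.cortexfold_sim <- function(x, ...) {
  last <- x$frames[[length(x$frames)]]
  cat(sprintf("<cortexfold simulation> %s geometry, %d frames, final t = %g d\n",
              x$config$geometry, length(x$frames), last$t))
  if (last$geometry == "bar")
    cat(sprintf("  final length %.1f um\n", last$length))
  invisible(x)
}

#' Current bar length of a simulation frame
#'
#' Distance between the fixed and free ends of the bar.
#'
#' @param frame A frame from a bar \code{cortexfold_sim}.
#' @return Length [um].
#' @export
measure_length <- function(frame) {
  if (!identical(frame$geometry, "bar"))
    stop("measure_length is defined for bar frames only", call. = FALSE)
  frame$length
}

#' Sample per-cohort density profiles from a bar frame
#'
#' Interpolates the spatial densities of each cohort at \code{n_points}
#' equispaced normalized positions along the current bar length.
#'
#' @param frame A bar simulation frame.
#' @param n_points Number of sample positions on [0, 1].
#' @param mesh The bar mesh of the simulation.
#' @return A data frame with columns \code{normalized_position},
#'   \code{c1}, \code{c2}, \code{c3} and attribute \code{length}.
#' @export
sample_profile <- function(frame, n_points = 60, mesh) {
  if (!identical(frame$geometry, "bar"))
    stop("sample_profile is defined for bar frames only", call. = FALSE)
  xcur <- mesh$x + frame$u
  L <- frame$length
  s <- seq(0, 1, length.out = n_points)
  xq <- s * L
  out <- data.frame(normalized_position = s)
  for (i in seq_len(ncol(frame$c_spatial)))
    out[[paste0("c", i)]] <- stats::approx(xcur, frame$c_spatial[, i], xq,
                                           rule = 2)$y
  attr(out, "length") <- L
  out
}

# RMS deviation of the outer-surface radius from its running circumferential
# mean (the onset criterion's raw statistic)
surface_deviation <- function(frame) {
  r <- sqrt(rowSums(frame$surface^2))
  n <- length(r)
  # window ~ a quarter of the circumference: wide enough that folding modes
  # (wavenumber >= ~3 on the half circle) survive the detrending
  win <- max(5L, 2L * (n %/% 8L) + 1L)
  half <- win %/% 2L
  pad <- c(rep(r[1], half), r, rep(r[n], half))
  run <- stats::filter(pad, rep(1 / win, win), sides = 2)
  run <- as.numeric(run)[(half + 1L):(half + n)]
  sqrt(mean((r - run)^2))
}
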