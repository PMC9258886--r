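# Folding metrics: onset of buckling, normalized wavelength, fiber fan-out,
# and the stiffness-ratio x growth-ratio parameter sweep.

#' Surface-deviation trace of a folding simulation
#'
#' RMS deviation of the outer-surface radius from its running
#' circumferential mean, per output frame.
#'
#' @param sim A half-circle \code{cortexfold_sim}.
#' @return Data frame with columns \code{t} and \code{deviation} [um].
#' @export
surface_trace <- function(sim) {
  stopifnot(inherits(sim, "cortexfold_sim"))
  fr <- Filter(function(f) identical(f$geometry, "halfcircle"), sim$frames)
  data.frame(t = vapply(fr, function(f) f$t, numeric(1)),
             deviation = vapply(fr, surface_deviation, numeric(1)))
}

#' Detect the onset of folding
#'
#' The onset is the first output time at which the RMS surface deviation
#' exceeds \code{threshold * R0}. Accepts either a simulation object or a
#' precomputed trace (data frame with \code{t}, \code{deviation}).
#'
#' @param x A half-circle \code{cortexfold_sim} or a trace data frame.
#' @param R0 Initial radius [um] (taken from the simulation if available).
#' @param threshold Deviation threshold as a fraction of \code{R0}.
#' @return Onset time [d], or \code{NA} if the surface never buckles.
#' @export
detect_onset <- function(x, R0 = NULL, threshold = 0.01) {
  if (inherits(x, "cortexfold_sim")) {
    trace <- surface_trace(x)
    if (is.null(R0)) R0 <- x$config$params$R0
  } else {
    trace <- x
    if (is.null(R0)) stop("'R0' is required with a plain trace", call. = FALSE)
  }
  if (nrow(trace) < 3) stop("need at least 3 frames to detect onset", call. = FALSE)
  hit <- which(trace$deviation > threshold * R0)
  if (length(hit) == 0) return(NA_real_)
  trace$t[hit[1]]
}

#' Dominant folding wavelength of a buckled surface
#'
#' Fits cosine modes \code{cos(k * theta)} to the surface radius along the
#' half circle, takes the dominant nonzero wavenumber \code{k*}, and
#' returns (arc length / k*) / R0.
#'
#' @param surface Two-column matrix of deformed surface coordinates
#'   (ordered along the arc), e.g. \code{frame$surface}.
#' @param R0 Initial radius [um].
#' @param k_max Largest wavenumber fitted.
#' @param k_min Smallest wavenumber eligible as the folding mode; the
#'   default skips k = 1, 2 (rigid drift and ovalization, not folds).
#' @return List with \code{k} (dominant mode), \code{wavelength_norm}
#'   (normalized wavelength), \code{arc_length} [um].
#' @export
measure_wavelength <- function(surface, R0, k_max = 12, k_min = 3) {
  r <- sqrt(rowSums(surface^2))
  th <- atan2(surface[, 2], surface[, 1])
  k_max <- min(k_max, floor(length(r) / 3))
  stopifnot(k_min >= 1, k_min <= k_max)
  X <- vapply(0:k_max, function(k) cos(k * th), numeric(length(th)))
  coefs <- stats::lm.fit(X, r)$coefficients
  amp <- abs(coefs[-1])
  amp[seq_len(k_min - 1)] <- 0
  if (max(amp) < 1e-9 * max(r))
    stop("flat surface: no dominant circumferential mode", call. = FALSE)
  k_star <- unname(which.max(amp))
  arc <- sum(sqrt(rowSums(diff(surface)^2)))
  list(k = k_star, wavelength_norm = (arc / k_star) / R0, arc_length = arc)
}

#' Fiber-orientation angles of a frame
#'
#' Angle between the deformed fiber \code{n = F N} and the referential
#' radial direction \code{N}, per element.
#'
#' @param frame A simulation frame.
#' @param mesh The mesh of the simulation.
#' @return Numeric vector of angles [rad].
#' @export
fiber_field <- function(frame, mesh) {
  n <- frame$fiber
  if (identical(frame$geometry, "bar")) return(rep(0, nrow(n)))
  Nref <- mesh$N
  dot <- abs(rowSums(n[, 1:2] * Nref[, 1:2]))
  nn <- sqrt(rowSums(n[, 1:2]^2))
  acos(pmin(dot / nn, 1))
}

#' Stiffness-ratio and growth-ratio sweep of the folding simulation
#'
#' Runs the half-circle simulation over a grid of cortex/subcortex
#' stiffness ratios and tangential/radial growth ratios, recording folding
#' onset and the normalized wavelength at onset. Individual run failures
#' are flagged and the sweep continues.
#'
#' @param base_config A half-circle \code{cortexfold_config} providing all
#'   settings other than the ratios.
#' @param beta_mu_grid Stiffness ratios.
#' @param beta_k_grid Tangential/radial growth ratios.
#' @param verbose Print one line per cell.
#' @return Data frame of class \code{cortexfold_sweep}: \code{beta_mu},
#'   \code{beta_k}, \code{onset} [d], \code{wavelength_norm}, \code{k},
#'   \code{max_deviation} [um], \code{ok}.
#' @export
run_sweep <- function(base_config, beta_mu_grid = c(3, 5, 7, 9),
                      beta_k_grid = c(1, 1.5, 2), verbose = FALSE) {
  stopifnot(inherits(base_config, "cortexfold_config"),
            base_config$geometry == "halfcircle")
  grid <- expand.grid(beta_mu = beta_mu_grid, beta_k = beta_k_grid)
  out <- cbind(grid, onset = NA_real_, wavelength_norm = NA_real_,
               k = NA_integer_, max_deviation = NA_real_, ok = FALSE)
  for (i in seq_len(nrow(grid))) {
    cfg <- base_config
    pl <- unclass(cfg$params)
    pl$beta_mu <- grid$beta_mu[i]
    pl$beta_k <- grid$beta_k[i]
    cfg$params <- validate_parameters(pl)
    sim <- tryCatch(run_simulation(cfg), error = function(e) NULL)
    if (is.null(sim)) {
      if (verbose) message(sprintf("beta_mu=%g beta_k=%g: run failed",
                                   grid$beta_mu[i], grid$beta_k[i]))
      next
    }
    tr <- surface_trace(sim)
    onset <- detect_onset(tr, R0 = cfg$params$R0,
                          threshold = cfg$onset_threshold)
    out$max_deviation[i] <- max(tr$deviation)
    out$ok[i] <- TRUE
    out$onset[i] <- onset
    if (!is.na(onset)) {
      fr <- Filter(function(f) f$t >= onset, sim$frames)[[1]]
      wl <- tryCatch(measure_wavelength(fr$surface, cfg$params$R0),
                     error = function(e) NULL)
      if (!is.null(wl)) {
        out$wavelength_norm[i] <- wl$wavelength_norm
        out$k[i] <- wl$k
      }
    }
    if (verbose)
      message(sprintf("beta_mu=%g beta_k=%g: onset %s, lambda/R0 %s",
                      grid$beta_mu[i], grid$beta_k[i],
                      format(out$onset[i]), format(out$wavelength_norm[i])))
  }
  class(out) <- c("cortexfold_sweep", class(out))
  out
}
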