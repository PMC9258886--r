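# Experiment-like synthetic inputs with known ground truth: density-profile
# datasets produced by the bar forward model (plus counting noise), and
# neuron coordinate tables drawn as inhomogeneous Poisson samples from a
# density profile. These are the test bed for the profiling and calibration
# machinery; no download or real imaging data is involved.

#' Configuration of the synthetic-data generator
#'
#' @param params Generating \code{cortexfold_params} (the ground truth).
#' @param noise \code{"none"}, \code{"poisson"} (counting noise on neuron
#'   numbers per profile bin; the default measurement model) or
#'   \code{"gaussian"} (multiplicative noise, for stress tests).
#' @param sigma Relative standard deviation of the Gaussian noise option.
#' @param W ROI width [um] (sets the counting volume of the Poisson noise).
#' @param dz Section thickness [um].
#' @param seed Integer RNG seed; recorded in the truth manifest.
#' @param n_points Points per profile.
#' @param n_elems,dt Forward-model discretization.
#' @return List of class \code{cortexfold_synth_config}.
#' @export
synthetic_config <- function(params = model_parameters(),
                             noise = c("poisson", "gaussian", "none"),
                             sigma = 0.1, W = 451, dz = 50, seed = 11L,
                             n_points = 60, n_elems = 60, dt = 0.05) {
  noise <- match.arg(noise)
  stopifnot(sigma >= 0, W > 0, dz > 0)
  structure(list(params = params, noise = noise, sigma = sigma, W = W,
                 dz = dz, seed = as.integer(seed), n_points = n_points,
                 n_elems = n_elems, dt = dt),
            class = "cortexfold_synth_config")
}

#' Generate a synthetic 8-profile dataset with truth manifest
#'
#' Runs the bar forward model at the generating parameters, samples the 8
#' (cohort, timepoint) density profiles and the 3 domain lengths, and
#' applies the configured measurement noise. With \code{noise = "none"} the
#' dataset equals the forward-model output exactly, so the calibration
#' objective at the generating parameters is zero.
#'
#' @param cfg \code{cortexfold_synth_config}.
#' @return List with \code{dataset} (a \code{cortexfold_dataset}) and
#'   \code{truth} (generating genome, seed, and settings).
#' @export
generate_profile_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "cortexfold_synth_config"))
  sim <- forward_bar_model(cfg$params, "three_cohort", n_elems = cfg$n_elems,
                           dt = cfg$dt, n_points = cfg$n_points)
  prof <- sim$profiles
  if (cfg$noise != "none") {
    prof <- with_seed(cfg$seed, {
      if (cfg$noise == "poisson") {
        # counting volume per profile bin at the relevant timepoint length
        lens <- sim$lengths
        binvol <- cfg$W * cfg$dz *
          lens$length_um[match(prof$timepoint, lens$timepoint)] /
          (cfg$n_points - 1)
        prof$density <- stats::rpois(nrow(prof), prof$density * binvol) / binvol
      } else {
        prof$density <- pmax(prof$density *
                               (1 + stats::rnorm(nrow(prof), 0, cfg$sigma)), 0)
      }
      prof
    })
  }
  truth <- list(genome = c(Gc = cfg$params$Gc, v_base = cfg$params$v_base,
                           d1 = cfg$params$delta_iv[1],
                           d2 = cfg$params$delta_iv[2],
                           d3 = cfg$params$delta_iv[3],
                           D = cfg$params$D, k_s = cfg$params$k_s),
                seed = cfg$seed, noise = cfg$noise, sigma = cfg$sigma,
                W = cfg$W, dz = cfg$dz, n_points = cfg$n_points,
                n_elems = cfg$n_elems, dt = cfg$dt)
  list(dataset = experimental_dataset(prof, sim$lengths, "three_cohort",
                                      strict = FALSE),
       truth = truth)
}

#' Draw a neuron coordinate table from a density profile
#'
#' Inhomogeneous Poisson point sample with intensity
#' \code{density(y) * W * dz} per unit ROI length; x uniform across the ROI
#' width. The inverse of the binning workflow, used for round-trip testing.
#'
#' @param profile Data frame with \code{normalized_position} and
#'   \code{density} [1/um^3], plus attribute (or argument) \code{L}.
#' @param W ROI width [um].
#' @param dz Section thickness [um].
#' @param seed Integer RNG seed.
#' @param L ROI length [um]; defaults to the profile's \code{length}
#'   attribute.
#' @return Data frame of class \code{cortexfold_neurons} with \code{x_um},
#'   \code{y_um}; the ROI dimensions are attached as attributes.
#' @export
generate_neuron_table <- function(profile, W = 451, dz = 50, seed = 11L,
                                  L = attr(profile, "length")) {
  stopifnot(!is.null(L), L > 0, all(profile$density >= 0))
  y <- profile$normalized_position * L
  lam <- profile$density * W * dz          # neurons per um of length
  with_seed(seed, {
    # piecewise-linear intensity: expected count per segment by trapezoid
    seg <- (lam[-1] + lam[-length(lam)]) / 2 * diff(y)
    n_seg <- stats::rpois(length(seg), seg)
    ys <- unlist(lapply(which(n_seg > 0), function(i) {
      # linear density within the segment via rejection-free inverse cdf
      u <- stats::runif(n_seg[i])
      a <- lam[i]; b <- lam[i + 1]
      w <- if (a + b > 0) {
        (sqrt(a^2 + u * (b^2 - a^2)) - a) / (b - a + (b == a)) * (a != b) +
          u * (a == b)
      } else u
      y[i] + w * (y[i + 1] - y[i])
    }))
    if (is.null(ys)) ys <- numeric(0)
    out <- data.frame(x_um = stats::runif(length(ys), 0, W), y_um = ys)
    attr(out, "W") <- W
    attr(out, "L") <- L
    attr(out, "dz") <- dz
    class(out) <- c("cortexfold_neurons", class(out))
    out
  })
}
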