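# Inverse calibration of the proliferation/migration/growth parameters
# {Gc, v, delta_1v..delta_3v, D, k_s} by a real-coded genetic algorithm
# minimizing a weighted density + length misfit between bar-model output
# and per-cohort experimental density profiles.

profile_keys <- function(mode = c("three_cohort", "leave_out_t3", "single_cohort")) {
  mode <- match.arg(mode)
  switch(mode,
         three_cohort = data.frame(cohort = c(1, 2, 1, 2, 3, 1, 2, 3),
                                   timepoint = c(1, 1, 2, 2, 2, 3, 3, 3)),
         leave_out_t3 = data.frame(cohort = c(1, 2, 1, 2, 3),
                                   timepoint = c(1, 1, 2, 2, 2)),
         single_cohort = data.frame(cohort = c(1, 1, 1), timepoint = c(1, 2, 3)))
}

#' Assemble an experimental-style dataset
#'
#' @param profiles Data frame with columns \code{cohort}, \code{timepoint},
#'   \code{normalized_position}, \code{density} (1/um^3). The three-cohort
#'   layout carries the 8 (cohort, timepoint) pairs \{(1,1), (2,1), (1,2),
#'   (2,2), (3,2), (1,3), (2,3), (3,3)\} -- cohort 3 is unobserved at the
#'   first timepoint.
#' @param lengths Data frame with columns \code{timepoint}, \code{length_um}
#'   (positive, increasing).
#' @param mode Dataset layout.
#' @param strict Require strictly increasing lengths over the timepoints
#'   (the invariant of real imaging data; model-generated datasets may
#'   relax it).
#' @return Object of class \code{cortexfold_dataset}.
#' @export
experimental_dataset <- function(profiles, lengths,
                                 mode = c("three_cohort", "leave_out_t3",
                                          "single_cohort"), strict = TRUE) {
  mode <- match.arg(mode)
  keys <- profile_keys(mode)
  have <- unique(profiles[, c("cohort", "timepoint")])
  if (nrow(merge(keys, have)) != nrow(keys))
    stop("dataset must contain exactly the (cohort, timepoint) pairs of mode ",
         mode, call. = FALSE)
  n_tp <- length(unique(keys$timepoint))
  lengths <- lengths[order(lengths$timepoint), ]
  if (nrow(lengths) != n_tp || any(lengths$length_um <= 0))
    stop("lengths must be positive", call. = FALSE)
  if (strict && is.unsorted(lengths$length_um))
    stop("lengths must be increasing over the timepoints", call. = FALSE)
  structure(list(profiles = profiles, lengths = lengths, mode = mode),
            class = "cortexfold_dataset")
}

resample_profile <- function(pos, dens, n = 60) {
  stats::approx(pos, dens, xout = seq(0, 1, length.out = n), rule = 2)$y
}

#' Calibration objective: weighted density + length misfit
#'
#' Sum over profile pairs of the relative Euclidean misfit
#' \code{||c_sim - c_exp|| / ||c_exp||}, weighted by \code{w1}, plus the sum
#' over timepoints of relative length errors weighted by \code{w2}. Profiles
#' are resampled to a common normalized grid before the norm is taken.
#'
#' @param sim Simulated dataset (\code{cortexfold_dataset} or the list
#'   returned by \code{\link{forward_bar_model}}).
#' @param exp_data Experimental \code{cortexfold_dataset}.
#' @param w1 Density-misfit weight (11/8 for the 8-profile layout).
#' @param w2 Length-misfit weight (11/3).
#' @param n_points Resampling grid size.
#' @return Nonnegative scalar.
#' @export
objective <- function(sim, exp_data, w1 = 11 / 8, w2 = 11 / 3, n_points = 60) {
  keys <- profile_keys(exp_data$mode)
  dens_err <- 0
  for (i in seq_len(nrow(keys))) {
    co <- keys$cohort[i]; tp <- keys$timepoint[i]
    pe <- exp_data$profiles[exp_data$profiles$cohort == co &
                            exp_data$profiles$timepoint == tp, ]
    ps <- sim$profiles[sim$profiles$cohort == co & sim$profiles$timepoint == tp, ]
    ce <- resample_profile(pe$normalized_position, pe$density, n_points)
    cs <- resample_profile(ps$normalized_position, ps$density, n_points)
    ne <- sqrt(sum(ce^2))
    if (ne == 0)
      stop("degenerate dataset: zero experimental profile for cohort ", co,
           ", timepoint ", tp, call. = FALSE)
    dens_err <- dens_err + sqrt(sum((cs - ce)^2)) / ne
  }
  le <- exp_data$lengths$length_um
  ls <- sim$lengths$length_um[match(exp_data$lengths$timepoint,
                                    sim$lengths$timepoint)]
  w1 * dens_err + w2 * sum(abs(ls - le) / le)
}

#' Run the bar forward model and extract the calibration observables
#'
#' @param params \code{cortexfold_params}.
#' @param mode Dataset layout (controls which profiles are extracted and how
#'   many cohorts are simulated).
#' @param n_elems,dt,n_points Discretization of the forward run and of the
#'   sampled profiles.
#' @param timepoints Simulation times of the experimental timepoints [d].
#' @return A \code{cortexfold_dataset} of simulated profiles and lengths.
#' @export
forward_bar_model <- function(params, mode = "three_cohort", n_elems = 60,
                              dt = 0.05, n_points = 60,
                              timepoints = c(8.5, 16.5, 27)) {
  n_coh <- if (mode == "single_cohort") 1L else 3L
  cfg <- simulation_config(params = params, geometry = "bar",
                           n_elems = n_elems, dt = dt,
                           timepoints = timepoints, n_cohorts = n_coh)
  sim <- run_simulation(cfg)
  keys <- profile_keys(mode)
  prof <- NULL
  lens <- NULL
  for (tp in sort(unique(keys$timepoint))) {
    fr <- Filter(function(f) abs(f$t - timepoints[tp]) < 1e-9, sim$frames)[[1]]
    sp <- sample_profile(fr, n_points, sim$mesh)
    lens <- rbind(lens, data.frame(timepoint = tp, length_um = attr(sp, "length")))
    for (co in keys$cohort[keys$timepoint == tp]) {
      prof <- rbind(prof, data.frame(cohort = co, timepoint = tp,
                                     normalized_position = sp$normalized_position,
                                     density = sp[[paste0("c", co)]]))
    }
  }
  experimental_dataset(prof, lens, mode, strict = FALSE)
}

#' Genetic-algorithm configuration
#'
#' Defaults: population 10, at most 40 generations, elitism of 1,
#' tournament selection of size 2, BLX-0.5 blend crossover with
#' probability 0.9, per-gene Gaussian mutation (sd = 10\% of the bound
#' range) with probability 0.2, convergence once the best objective
#' improves by less than \code{plateau_tol} over \code{plateau_gens}
#' generations.
#'
#' @param pop_size,max_generations,elite,tournament,p_crossover,blx_alpha
#'   GA operator settings.
#' @param p_mutation,mutation_sd Per-gene mutation probability and sd as a
#'   fraction of each bound range.
#' @param plateau_tol,plateau_gens Convergence rule.
#' @param expand_bounds Fractional widening of the initial-population
#'   bounds (0, 0.5, 0.75, 1.0 or 1.25 reproduce the robustness study).
#' @param n_elems,dt,n_points Forward-model discretization.
#' @return List of class \code{cortexfold_ga_config}.
#' @export
ga_config <- function(pop_size = 10, max_generations = 40, elite = 1,
                      tournament = 2, p_crossover = 0.9, blx_alpha = 0.5,
                      p_mutation = 0.2, mutation_sd = 0.1,
                      plateau_tol = 1e-3, plateau_gens = 10,
                      expand_bounds = 0, n_elems = 60, dt = 0.05,
                      n_points = 60) {
  structure(as.list(environment()), class = "cortexfold_ga_config")
}

#' Parameter bounds of the calibration genome
#'
#' Literature ranges for the division rate, migration velocity and
#' diffusion coefficient; geometric bounds for the destinations (within the
#' cortical-plate side of the material domain) and the growth parameter.
#'
#' @param params Baseline parameters (for R0).
#' @param mode Genome layout.
#' @return Matrix with rows = genes, columns \code{lower}, \code{upper}.
#' @export
genome_bounds <- function(params = model_parameters(),
                          mode = c("three_cohort", "leave_out_t3",
                                   "single_cohort")) {
  mode <- match.arg(mode)
  b <- rbind(Gc = c(1.0e-6, 1.5e-5),
             v_base = c(230, 4752),
             d1 = c(0.6, 0.98) * params$R0,
             d2 = c(0.6, 0.98) * params$R0,
             d3 = c(0.6, 0.98) * params$R0,
             D = c(25000, 35000),
             k_s = c(1e5, 3.2e5))
  colnames(b) <- c("lower", "upper")
  if (mode == "single_cohort") {
    b <- b[c("Gc", "v_base", "d1", "D", "k_s"), ]
    rownames(b)[3] <- "dv"
    # one cohort must supply the production of all three, so its division
    # rate may exceed the per-cohort literature range
    b["Gc", "upper"] <- 5e-5
  }
  b
}

genome_to_params <- function(genome, base, mode) {
  pl <- unclass(base)
  pl$Gc <- unname(genome["Gc"])
  pl$v_base <- unname(genome["v_base"])
  pl$D <- unname(genome["D"])
  pl$k_s <- unname(genome["k_s"])
  if (mode == "single_cohort") {
    dv <- unname(genome["dv"])
    pl$delta_iv <- c(dv, dv + 1, dv + 2)   # only cohort 1 is simulated
  } else {
    pl$delta_iv <- sort(unname(genome[c("d1", "d2", "d3")]))
  }
  validate_parameters(pl)
}

#' One generation of the real-coded genetic algorithm
#'
#' Elitism, tournament selection, BLX-alpha blend crossover, per-gene
#' Gaussian mutation, and clipping to the bounds. Destination genes of the
#' three-cohort genome are kept sorted. Deterministic given the R RNG
#' state.
#'
#' @param population Matrix (individuals x genes, named columns).
#' @param fitness Objective values (smaller is better).
#' @param bounds Bounds matrix from \code{\link{genome_bounds}}.
#' @param config \code{cortexfold_ga_config}.
#' @return Matrix of the next generation.
#' @export
evolve <- function(population, fitness, bounds, config = ga_config()) {
  n <- nrow(population)
  if (is.null(n) || n == 0) stop("empty population", call. = FALSE)
  rng_range <- bounds[, "upper"] - bounds[, "lower"]
  ord <- order(fitness)
  nxt <- population[rep(ord[1], n), , drop = FALSE]   # elite seeds row 1
  pick <- function() {
    cand <- sample.int(n, config$tournament, replace = TRUE)
    cand[which.min(fitness[cand])]
  }
  i <- config$elite
  while (i < n) {
    p1 <- population[pick(), ]
    p2 <- population[pick(), ]
    if (stats::runif(1) < config$p_crossover) {
      lo <- pmin(p1, p2) - config$blx_alpha * abs(p1 - p2)
      hi <- pmax(p1, p2) + config$blx_alpha * abs(p1 - p2)
      ch1 <- stats::setNames(stats::runif(length(p1), lo, hi), names(p1))
      ch2 <- stats::setNames(stats::runif(length(p1), lo, hi), names(p1))
    } else {
      ch1 <- p1; ch2 <- p2
    }
    for (ch in list(ch1, ch2)) {
      if (i >= n) break
      mut <- stats::runif(length(ch)) < config$p_mutation
      ch[mut] <- ch[mut] + stats::rnorm(sum(mut), 0,
                                        config$mutation_sd * rng_range[mut])
      ch <- pmin(pmax(ch, bounds[, "lower"]), bounds[, "upper"])
      dsort <- intersect(c("d1", "d2", "d3"), colnames(population))
      if (length(dsort) == 3) ch[dsort] <- sort(ch[dsort])
      i <- i + 1
      nxt[i, ] <- ch
    }
  }
  nxt
}

#' Calibrate the model to a density-profile dataset
#'
#' Genetic-algorithm minimization of \code{\link{objective}} with the bar
#' forward model. Forward evaluations are cached by genome. A failed
#' forward run is assigned a large penalty and logged.
#'
#' @param dataset \code{cortexfold_dataset}.
#' @param mode \code{"three_cohort"} (full fit), \code{"leave_out_t3"}
#'   (calibrate on the first two timepoints), or \code{"single_cohort"}
#'   (one cohort fit to summed densities).
#' @param config \code{cortexfold_ga_config}.
#' @param base_params Baseline \code{cortexfold_params} for non-calibrated
#'   entries.
#' @param seed Integer RNG seed.
#' @param verbose Print a line per generation.
#' @return List of class \code{cortexfold_calibration}: \code{best_genome},
#'   \code{best_objective}, \code{trace} (per-generation best/mean),
#'   \code{population}, \code{failures}, \code{mode}.
#' @export
calibrate <- function(dataset, mode = c("three_cohort", "leave_out_t3",
                                        "single_cohort"),
                      config = ga_config(), base_params = model_parameters(),
                      seed = 1L, verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "cortexfold_dataset"))
  if (dataset$mode != mode)
    stop("dataset layout '", dataset$mode, "' does not match mode '", mode,
         "'", call. = FALSE)
  bounds <- genome_bounds(base_params, mode)
  init_b <- bounds
  if (config$expand_bounds > 0) {
    mid <- rowMeans(init_b)
    half <- (init_b[, "upper"] - init_b[, "lower"]) / 2 * (1 + config$expand_bounds)
    init_b[, "lower"] <- pmax(mid - half, 1e-12)
    init_b[, "upper"] <- mid + half
  }
  w1 <- if (mode == "single_cohort") 11 / 3 else 11 / 8
  cache <- new.env(parent = emptyenv())
  failures <- 0L
  eval_genome <- function(g) {
    key <- paste(signif(g, 12), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- tryCatch({
      p <- genome_to_params(g, base_params, mode)
      sim <- forward_bar_model(p, mode, n_elems = config$n_elems,
                               dt = config$dt, n_points = config$n_points)
      objective(sim, dataset, w1 = w1, n_points = config$n_points)
    }, error = function(e) {
      failures <<- failures + 1L
      1e6
    })
    cache[[key]] <- val
    val
  }

  set.seed(seed)
  ng <- nrow(bounds)
  pop <- matrix(stats::runif(config$pop_size * ng,
                             rep(init_b[, "lower"], each = config$pop_size),
                             rep(init_b[, "upper"], each = config$pop_size)),
                nrow = config$pop_size, dimnames = list(NULL, rownames(bounds)))
  if (mode != "single_cohort")
    pop[, c("d1", "d2", "d3")] <- t(apply(pop[, c("d1", "d2", "d3")], 1, sort))
  trace <- NULL
  best <- Inf
  best_genome <- pop[1, ]
  for (gen in seq_len(config$max_generations)) {
    fit <- apply(pop, 1, eval_genome)
    if (min(fit) < best) {
      best <- min(fit)
      best_genome <- pop[which.min(fit), ]
    }
    trace <- rbind(trace, data.frame(generation = gen, best = best,
                                     gen_best = min(fit), gen_mean = mean(fit)))
    if (verbose)
      message(sprintf("gen %2d: best %.4f (mean %.2f)", gen, best, mean(fit)))
    if (gen > config$plateau_gens &&
        trace$best[gen - config$plateau_gens] - best < config$plateau_tol)
      break
    pop <- evolve(pop, fit, bounds, config)
  }
  structure(list(best_genome = best_genome, best_objective = best,
                 trace = trace, population = pop, failures = failures,
                 mode = mode, bounds = bounds),
            class = "cortexfold_calibration")
}

#' @export
print.cortexfold_calibration <- function(x, ...) {
  cat(sprintf("<cortexfold calibration> mode %s, %d generations, best f_obj %.4f\n",
              x$mode, nrow(x$trace), x$best_objective))
  print(signif(x$best_genome, 4))
  invisible(x)
}

#' Two-parameter sensitivity scan of the calibration objective
#'
#' Evaluates the objective on a grid of relative perturbations of two
#' genome entries around a center point, all other entries held fixed.
#'
#' @param center Named genome vector (e.g. the calibrated optimum).
#' @param pair Character vector of two gene names, e.g.
#'   \code{c("Gc", "D")}.
#' @param dataset \code{cortexfold_dataset} to score against.
#' @param rel_grid Relative factors applied to each of the two genes.
#' @param config \code{cortexfold_ga_config} (forward-model settings).
#' @param base_params Baseline parameters.
#' @param mode Dataset layout.
#' @return Data frame with the two gene values and \code{f_obj}.
#' @export
sensitivity_scan <- function(center, pair, dataset,
                             rel_grid = seq(0.8, 1.2, length.out = 5),
                             config = ga_config(), base_params = model_parameters(),
                             mode = "three_cohort") {
  stopifnot(length(pair) == 2, all(pair %in% names(center)))
  w1 <- if (mode == "single_cohort") 11 / 3 else 11 / 8
  out <- expand.grid(f1 = rel_grid, f2 = rel_grid)
  out[[pair[1]]] <- center[pair[1]] * out$f1
  out[[pair[2]]] <- center[pair[2]] * out$f2
  out$f_obj <- NA_real_
  for (i in seq_len(nrow(out))) {
    g <- center
    g[pair[1]] <- out[[pair[1]]][i]
    g[pair[2]] <- out[[pair[2]]][i]
    out$f_obj[i] <- tryCatch({
      p <- genome_to_params(g, base_params, mode)
      sim <- forward_bar_model(p, mode, n_elems = config$n_elems,
                               dt = config$dt, n_points = config$n_points)
      objective(sim, dataset, w1 = w1, n_points = config$n_points)
    }, error = function(e) NA_real_)
  }
  out
}
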