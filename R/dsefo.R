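# Electric Fish Optimization (EFO) and its distance-sorted variant (DS-EFO):
# a bounded continuous minimizer. Individuals carry a position, a fitness, a
# rank-derived frequency and a smoothed amplitude; good individuals perform
# local "active electrolocation" moves, the rest contract towards an
# amplitude-weighted reference ("passive electrolocation"). DS-EFO selects
# the mode by comparing each individual's distance to the current best with
# the population mean of those distances.

#' Parameters for the electric fish optimizer
#'
#' @param bounds 2-row matrix: row 1 lower, row 2 upper bound per dimension.
#' @param pop_size population size (>= 2).
#' @param iterations number of iterations.
#' @param fr_min,fr_max frequency range (defaults 0 and 1).
#' @param beta amplitude memory weight in `[0, 1]` (default 0.3, chosen by
#'   pilot convergence studies on standard quadratic test functions).
#' @param reinit_prob probability of resampling one random coordinate of a
#'   candidate move.
#' @param nk number of reference individuals for the passive move.
#' @param seed integer seed.
#' @return list of class `efo_params`.
#' @export
efo_params <- function(bounds, pop_size = 10, iterations = 100,
                       fr_min = 0, fr_max = 1, beta = 0.3,
                       reinit_prob = 0.1, nk = 3, seed = 1) {
  bounds <- as.matrix(bounds)
  if (nrow(bounds) != 2 || any(bounds[1, ] > bounds[2, ]))
    stop_arg("`bounds` must be a 2 x d matrix with lower <= upper")
  pop_size <- check_count(pop_size, "pop_size", min = 2L)
  iterations <- check_count(iterations, "iterations")
  if (fr_min >= fr_max) stop_arg("`fr_min` must be < `fr_max`")
  if (beta < 0 || beta > 1) stop_arg("`beta` must lie in [0, 1]")
  if (reinit_prob < 0 || reinit_prob > 1) stop_arg("`reinit_prob` must lie in [0, 1]")
  structure(list(bounds = bounds, pop_size = pop_size, iterations = iterations,
                 fr_min = fr_min, fr_max = fr_max, beta = beta,
                 reinit_prob = reinit_prob, nk = check_count(nk, "nk"),
                 seed = as.integer(seed)),
            class = "efo_params")
}

clip_bounds <- function(x, bounds) pmin(pmax(x, bounds[1, ]), bounds[2, ])

#' Initialize a population uniformly within the bounds
#'
#' Positions are `lower + U(0,1) * (upper - lower)` per coordinate; fitness is
#' evaluated; initial frequency and amplitude follow from the fitness ranks.
#'
#' @param params an [efo_params()].
#' @param objective function mapping a position vector to a finite value
#'   (minimized).
#' @return list of class `efo_population` with `positions` (pop x d matrix),
#'   `fitness`, `frequency`, `amplitude`, `evaluations`.
#' @export
init_population <- function(params, objective) {
  d <- ncol(params$bounds)
  pos <- with_seed(derive_seed(params$seed, "init"), {
    delta <- matrix(stats::runif(params$pop_size * d), params$pop_size, d)
    sweep(sweep(delta, 2L, params$bounds[2, ] - params$bounds[1, ], "*"),
          2L, params$bounds[1, ], "+")
  })
  fit <- apply(pos, 1L, objective)
  if (any(!is.finite(fit))) {
    warning("objective returned non-finite values at initialization; using a large sentinel")
    fit[!is.finite(fit)] <- .Machine$double.xmax / 4
  }
  pop <- structure(list(positions = pos, fitness = fit,
                        frequency = rep(params$fr_max, params$pop_size),
                        amplitude = rep(params$fr_max, params$pop_size),
                        evaluations = params$pop_size),
                   class = "efo_population")
  pop <- update_frequencies(pop, params)
  pop$amplitude <- pop$frequency     # initial amplitude equals initial frequency
  pop
}

#' Map fitness values to frequencies
#'
#' Linear map on fitness: the best (lowest) fitness gets `fr_max`, the worst
#' gets `fr_min`. When all fitness values are equal every frequency is set to
#' `fr_max` (documented convention). The map is invariant under affine
#' rescaling of the fitness values.
#'
#' @param population an `efo_population`.
#' @param params an [efo_params()].
#' @return the population with updated `frequency`.
#' @export
update_frequencies <- function(population, params) {
  f <- population$fitness
  worst <- max(f); best <- min(f)
  population$frequency <- if (worst == best) {
    rep(params$fr_max, length(f))
  } else {
    params$fr_min + ((worst - f) / (worst - best)) * (params$fr_max - params$fr_min)
  }
  population
}

#' Smooth amplitudes towards the current frequencies
#'
#' `amp <- beta * amp_prev + (1 - beta) * fr`: `beta = 0` tracks the frequency
#' exactly, `beta = 1` freezes the amplitude.
#'
#' @inheritParams update_frequencies
#' @return the population with updated `amplitude`.
#' @export
update_amplitudes <- function(population, params) {
  population$amplitude <- params$beta * population$amplitude +
    (1 - params$beta) * population$frequency
  population
}

#' Active range of an individual
#'
#' Mean over dimensions of the bound width, scaled by the individual's
#' amplitude.
#'
#' @param amplitude the individual's amplitude.
#' @param params an [efo_params()].
#' @return a nonnegative scalar.
#' @export
active_range <- function(amplitude, params) {
  mean(params$bounds[2, ] - params$bounds[1, ]) * amplitude
}

#' Cartesian (Euclidean) distance between two positions
#' @param a,b numeric vectors of equal length.
#' @export
efo_distance <- function(a, b) sqrt(sum((a - b)^2))

#' Active electrolocation move
#'
#' Isotropic local search: each coordinate is displaced by `U(-1, 1)` times
#' the active range, then clipped to the bounds.
#'
#' @param position current position vector.
#' @param ar active range (scalar).
#' @param params an [efo_params()].
#' @return proposed position.
#' @export
active_move <- function(position, ar, params) {
  d <- length(position)
  clip_bounds(position + stats::runif(d, -1, 1) * ar, params$bounds)
}

#' Passive electrolocation move
#'
#' Selection weights proportional to `amplitude / distance` over the active
#' individuals choose `nk` reference individuals; their amplitude-weighted
#' mean position is the reference, and the move contracts towards it by a
#' per-coordinate `U(0, 1)` factor (clipped to bounds). With an empty active
#' set the caller falls back to [active_move()].
#'
#' @param position current position.
#' @param active_positions matrix of active individuals' positions.
#' @param active_amplitudes their amplitudes.
#' @param params an [efo_params()].
#' @return proposed position.
#' @export
passive_move <- function(position, active_positions, active_amplitudes, params) {
  na <- nrow(active_positions)
  if (na == 0) stop_arg("empty active set; use active_move fallback")
  dists <- sqrt(rowSums((active_positions - matrix(position, na, length(position),
                                                   byrow = TRUE))^2))
  w <- active_amplitudes / (dists + 1e-12)
  nk <- min(params$nk, na)
  sel <- if (na == 1) 1L else sample.int(na, nk, prob = w / sum(w))
  amp <- active_amplitudes[sel]
  ref <- colSums(active_positions[sel, , drop = FALSE] * amp) / sum(amp)
  delta <- stats::runif(length(position))
  clip_bounds(position + delta * (ref - position), params$bounds)
}

#' Stochastic coordinate reinitialization
#'
#' With probability `reinit_prob` one uniformly chosen coordinate is resampled
#' uniformly within its bounds.
#'
#' @param position current position.
#' @param params an [efo_params()].
#' @return the (possibly modified) position.
#' @export
stochastic_reinit <- function(position, params) {
  if (stats::runif(1) <= params$reinit_prob) {
    q <- sample.int(length(position), 1L)
    position[q] <- params$bounds[1, q] +
      stats::runif(1) * (params$bounds[2, q] - params$bounds[1, q])
  }
  position
}

#' Distance-sorted mode selection
#'
#' Computes each individual's distance to the current best; individual `i`
#' goes active iff its distance is strictly below the population mean of
#' those distances AND at least one other individual lies within its active
#' range. With all individuals coincident the mean distance is 0 and the
#' strict inequality makes everyone passive.
#'
#' @param i individual index.
#' @param population an `efo_population`.
#' @param params an [efo_params()].
#' @return `"active"` or `"passive"`.
#' @export
dsefo_select_mode <- function(i, population, params) {
  pos <- population$positions
  best <- which.min(population$fitness)
  dbest <- sqrt(rowSums((pos - matrix(pos[best, ], nrow(pos), ncol(pos),
                                      byrow = TRUE))^2))
  ar <- active_range(population$amplitude[i], params)
  di <- sqrt(rowSums((pos - matrix(pos[i, ], nrow(pos), ncol(pos), byrow = TRUE))^2))
  has_neighbor <- any(di[-i] <= ar)
  if (dbest[i] < mean(dbest) && has_neighbor) "active" else "passive"
}

# Mode selection for one whole iteration (vectorized over individuals).
select_modes <- function(population, params, variant) {
  np <- nrow(population$positions)
  pos <- population$positions
  best <- which.min(population$fitness)
  dbest <- sqrt(rowSums((pos - matrix(pos[best, ], np, ncol(pos), byrow = TRUE))^2))
  mean_d <- mean(dbest)
  vapply(seq_len(np), function(i) {
    ar <- active_range(population$amplitude[i], params)
    di <- sqrt(rowSums((pos - matrix(pos[i, ], np, ncol(pos), byrow = TRUE))^2))
    has_neighbor <- any(di[-i] <= ar)
    if (variant == "DS-EFO") {
      if (dbest[i] < mean_d && has_neighbor) "active" else "passive"
    } else {
      # plain EFO: higher-frequency individuals tend to the active mode
      if (stats::runif(1) < population$frequency[i] && has_neighbor)
        "active" else "passive"
    }
  }, character(1))
}

#' Run the electric fish optimizer
#'
#' Greedy minimization: per iteration each individual proposes one candidate
#' (active or passive move plus possible coordinate reinitialization) which
#' is accepted only if it improves the individual's fitness, so the best-
#' so-far is never lost and the objective is evaluated exactly
#' `pop_size * (1 + iterations)` times. Candidates with non-finite objective
#' values are rejected with a warning.
#'
#' @param objective function: numeric vector -> scalar, minimized.
#' @param params an [efo_params()].
#' @param variant `"DS-EFO"` (distance-sorted mode rule, the default) or
#'   `"EFO"` (frequency-based mode rule).
#' @return list with `best_position`, `best_fitness`, `trace` (data frame with
#'   per-iteration best fitness) and `evaluations`.
#' @export
efo_optimize <- function(objective, params, variant = c("DS-EFO", "EFO")) {
  variant <- match.arg(variant)
  pop <- init_population(params, objective)
  evals <- pop$evaluations
  trace_fit <- numeric(params$iterations + 1L)
  trace_fit[1L] <- min(pop$fitness)
  d <- ncol(params$bounds)
  with_seed(derive_seed(params$seed, "run", variant), {
    for (tf in seq_len(params$iterations)) {
      pop <- update_frequencies(pop, params)
      pop <- update_amplitudes(pop, params)
      modes <- select_modes(pop, params, variant)
      active_idx <- which(modes == "active")
      act_pos <- pop$positions[active_idx, , drop = FALSE]
      act_amp <- pop$amplitude[active_idx]
      # local-search step radius: the electrosensory range (bound width x
      # amplitude) gates the mode choice, but the *move* anneals with the
      # swarm's current spread so refinement is possible near convergence
      best <- which.min(pop$fitness)
      dbest <- sqrt(rowSums((pop$positions -
        matrix(pop$positions[best, ], params$pop_size, d, byrow = TRUE))^2))
      step_scale <- 2 * mean(dbest) / sqrt(d)
      for (i in seq_len(params$pop_size)) {
        ar <- step_scale * pop$amplitude[i]
        cand <- if (modes[i] == "active" || length(active_idx) == 0) {
          active_move(pop$positions[i, ], ar, params)
        } else {
          passive_move(pop$positions[i, ], act_pos, act_amp, params)
        }
        cand <- stochastic_reinit(cand, params)
        f <- objective(cand)
        evals <- evals + 1L
        if (!is.finite(f)) {
          warning("objective returned a non-finite value; candidate rejected")
        } else if (f < pop$fitness[i]) {
          pop$positions[i, ] <- cand
          pop$fitness[i] <- f
        }
      }
      trace_fit[tf + 1L] <- min(pop$fitness)
    }
  })
  best <- which.min(pop$fitness)
  list(best_position = pop$positions[best, ],
       best_fitness = pop$fitness[best],
       trace = data.frame(iteration = 0:params$iterations,
                          best_fitness = trace_fit),
       evaluations = evals)
}
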