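#' @title Base FOX optimizer primitives
#' @description The fox-hunting metaheuristic models a red fox locating prey
#'   under snow by sound. Per agent it keeps a vector of simulated sound
#'   travel times in `[0, 1]`; from these it derives the sound speed toward
#'   the best-known position, the fox-prey distance, and a jump height, which
#'   together produce the exploitation move. Exploration is a random walk
#'   scaled by the best position, the population-minimum mean travel time,
#'   and a coefficient that decays over iterations.
#' @name fox-core
NULL

TIME_FLOOR <- 1e-12

#' Sound speed toward the best position
#'
#' Element-wise division of the best-known position by the agent's sound
#' travel times. Times are floored at `1e-12` so a zero travel time can never
#' produce a division fault.
#'
#' @param best_x Best-known position vector.
#' @param time_row The agent's travel-time vector (same length).
#' @return Numeric vector `best_x / time_row`.
#' @examples
#' compute_sound_speed(c(343), c(1))
#' @export
compute_sound_speed <- function(best_x, time_row) {
  if (length(best_x) != length(time_row)) {
    stop("`best_x` and `time_row` must have the same length", call. = FALSE)
  }
  best_x / pmax(time_row, TIME_FLOOR)
}

#' Sound-travel and fox-prey distances
#'
#' The sound-travel distance is speed times time; the fox-prey distance is
#' half of it (the sound makes a round trip).
#'
#' @param sp_s Sound-speed vector (from [compute_sound_speed()]).
#' @param time_row Travel-time vector of the same length.
#' @return A list with `dist_s_t` and `dist_fox_prey`.
#' @examples
#' compute_distances(c(10, 20), c(0.5, 0.5))
#' @export
compute_distances <- function(sp_s, time_row) {
  if (length(sp_s) != length(time_row)) {
    stop("`sp_s` and `time_row` must have the same length", call. = FALSE)
  }
  dist_s_t <- sp_s * time_row
  list(dist_s_t = dist_s_t, dist_fox_prey = 0.5 * dist_s_t)
}

#' Jump height for the exploitation pounce
#'
#' The mean travel time `tt` is halved to get the one-way mean time `t`; the
#' jump is the ballistic height `0.5 * g * t^2`.
#'
#' @param time_row Travel-time vector for the agent (non-empty).
#' @param gravity Gravitational acceleration (default 9.81).
#' @return Scalar jump height.
#' @examples
#' compute_jump(c(1, 1))  # 0.5 * 9.81 * 0.25
#' @export
compute_jump <- function(time_row, gravity = 9.81) {
  if (length(time_row) < 1L) stop("`time_row` must be non-empty", call. = FALSE)
  t_half <- mean(time_row) / 2
  0.5 * gravity * t_half^2
}

#' Exploitation move
#'
#' The candidate position is the fox-prey distance scaled by the jump height
#' and a direction coefficient: `c1` for a northeast jump (`p > p_threshold`)
#' or `c2` for the opposite direction.
#'
#' @param dist_fox_prey Fox-prey distance vector.
#' @param jump Scalar jump height.
#' @param p Uniform draw in `[0, 1]` selecting the direction.
#' @param config A [fox_config()] supplying `c1`, `c2` and `p_threshold`.
#' @return Candidate position vector.
#' @examples
#' exploitation_move(c(2, 2), 1, p = 0.5, fox_config())
#' @export
exploitation_move <- function(dist_fox_prey, jump, p, config = fox_config()) {
  stopifnot(inherits(config, "fox_config"))
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]", call. = FALSE)
  coef <- if (p > config$p_threshold) config$c1 else config$c2
  dist_fox_prey * jump * coef
}

#' Population-minimum mean travel time
#'
#' Row means of the travel-time matrix give each agent's mean time `tt`;
#' the minimum over agents controls the exploration step size.
#'
#' @param time_matrix Agents-by-dimensions travel-time matrix.
#' @return Scalar minimum of the row means.
#' @examples
#' compute_min_t(rbind(c(0.2, 0.4), c(0.6, 0.8)))
#' @export
compute_min_t <- function(time_matrix) {
  if (!is.matrix(time_matrix) || nrow(time_matrix) < 1L || ncol(time_matrix) < 1L) {
    stop("`time_matrix` must be a non-empty matrix", call. = FALSE)
  }
  min(rowMeans(time_matrix))
}

#' Exploration-control coefficient
#'
#' Decays linearly from 2 toward 0 over the run: `a = 2 * (1 - it/max_iter)`,
#' shrinking the exploration radius as the search matures. The literal
#' alternative `2 * (it - 1/max_iter)` grows with `it` and is available via
#' `legacy = TRUE` for comparison runs only.
#'
#' @param it Current iteration, `1..max_iter`.
#' @param max_iter Total iterations.
#' @param legacy Use the increasing literal form (default `FALSE`).
#' @return Scalar coefficient.
#' @examples
#' compute_a(50, 200)   # 1.5
#' compute_a(200, 200)  # 0
#' @export
compute_a <- function(it, max_iter, legacy = FALSE) {
  if (it < 1 || it > max_iter) {
    stop("`it` must lie in [1, max_iter]", call. = FALSE)
  }
  if (isTRUE(legacy)) 2 * (it - 1 / max_iter) else 2 * (1 - it / max_iter)
}

#' Exploration move (uniform random walk)
#'
#' The candidate position is the best-known position scaled component-wise by
#' fresh uniform draws and by `min_t * a`.
#'
#' @param best_x Best-known position vector.
#' @param min_t Population-minimum mean travel time (see [compute_min_t()]).
#' @param a Exploration-control coefficient (see [compute_a()]).
#' @return Candidate position vector.
#' @examples
#' set.seed(1)
#' exploration_move(c(1, 1), min_t = 1, a = 1)
#' @export
exploration_move <- function(best_x, min_t, a) {
  if (min_t < 0 || a < 0) stop("`min_t` and `a` must be non-negative", call. = FALSE)
  best_x * stats::runif(length(best_x)) * (min_t * a)
}

#' Initialize the FOX population
#'
#' Positions are sampled uniformly inside the box, the objective is evaluated
#' for every agent, the best agent seeds the elite archive, and the
#' travel-time matrix is freshly sampled in `[0, 1]`.
#'
#' @param objective Function mapping a numeric vector to a finite scalar
#'   (minimization).
#' @param bounds A [bounds()] object.
#' @param config A [fox_config()].
#' @return An object of class `fox_state`: a list with `positions`,
#'   `fitness`, `time_matrix`, `best_x`, `best_fitness`, `iteration`
#'   and `n_evals`.
#' @export
init_population <- function(objective, bounds, config = fox_config()) {
  stopifnot(inherits(bounds, "fox_bounds"), inherits(config, "fox_config"))
  n <- config$n_agents
  positions <- sample_in_bounds(n, bounds)
  fitness <- apply(positions, 1L, objective)
  if (any(!is.finite(fitness))) {
    warning("objective returned non-finite values at initialization; treated as +Inf")
    fitness[!is.finite(fitness)] <- Inf
  }
  time_matrix <- matrix(pmax(stats::runif(n * bounds$dim), TIME_FLOOR), n, bounds$dim)
  ibest <- which.min(fitness)
  structure(
    list(
      positions = positions,
      fitness = as.numeric(fitness),
      time_matrix = time_matrix,
      best_x = positions[ibest, ],
      best_fitness = fitness[ibest],
      iteration = 0L,
      n_evals = n
    ),
    class = "fox_state"
  )
}

# One iteration of the population update, shared by FOX and CFOA.
# levy = NULL gives the uniform exploration walk; a levy_params object swaps
# in Levy steps. Draw order per iteration is fixed: the full time matrix,
# then r (n), then p (n), then the full n x dim exploration multiplier block
# (drawn whether or not every row explores, so the stream advance does not
# depend on the branch outcomes).
step_population <- function(state, objective, bounds, config, levy = NULL) {
  n <- config$n_agents
  d <- bounds$dim
  it <- state$iteration + 1L

  time_matrix <- matrix(pmax(stats::runif(n * d), TIME_FLOOR), n, d)
  r <- stats::runif(n)
  p <- stats::runif(n)
  walk <- if (is.null(levy)) {
    matrix(stats::runif(n * d), n, d)
  } else {
    levy_step_matrix(n, d, levy)
  }

  best_rep <- matrix(state$best_x, n, d, byrow = TRUE)
  sp_s <- best_rep / time_matrix
  dist_s_t <- sp_s * time_matrix
  dist_fox_prey <- 0.5 * dist_s_t
  jump <- 0.5 * config$gravity * (rowMeans(time_matrix) / 2)^2
  coef <- ifelse(p > config$p_threshold, config$c1, config$c2)

  min_t <- compute_min_t(time_matrix)
  a <- compute_a(it, config$max_iter, legacy = config$legacy_a)

  exploit <- r >= config$r_threshold
  new_pos <- best_rep * walk * (min_t * a)
  if (any(exploit)) {
    new_pos[exploit, ] <- dist_fox_prey[exploit, , drop = FALSE] *
      (jump[exploit] * coef[exploit])
  }
  new_pos <- clamp_to_bounds(new_pos, bounds)

  new_fit <- apply(new_pos, 1L, objective)
  bad <- !is.finite(new_fit)
  if (any(bad)) {
    warning(sprintf("objective returned non-finite fitness for %d agent(s); previous fitness kept", sum(bad)))
    new_fit[bad] <- state$fitness[bad]
  }

  state$positions <- new_pos
  state$fitness <- as.numeric(new_fit)
  state$time_matrix <- time_matrix
  ibest <- which.min(state$fitness)
  if (state$fitness[ibest] < state$best_fitness) {
    state$best_fitness <- state$fitness[ibest]
    state$best_x <- state$positions[ibest, ]
  }
  state$iteration <- it
  state$n_evals <- state$n_evals + n
  state
}

#' Advance the FOX population by one iteration
#'
#' Per agent: the travel-time row is resampled, a uniform draw `r` selects
#' exploitation (`r >= r_threshold`) or exploration, the corresponding move
#' produces a candidate which is clamped to the box and evaluated, and the
#' position is replaced unconditionally. The elite best position/fitness is
#' updated only on improvement, so it never worsens.
#'
#' @inheritParams init_population
#' @param state A `fox_state` from [init_population()] or a previous step.
#' @return The updated `fox_state`.
#' @export
fox_step <- function(state, objective, bounds, config = fox_config()) {
  stopifnot(inherits(state, "fox_state"))
  step_population(state, objective, bounds, config, levy = NULL)
}

run_optimizer_loop <- function(objective, bounds, config, levy = NULL,
                               elimination = NULL, algorithm = "fox") {
  state <- init_population(objective, bounds, config)
  history <- numeric(config$max_iter)
  n_elim_events <- 0L
  for (it in seq_len(config$max_iter)) {
    state <- step_population(state, objective, bounds, config, levy = levy)
    if (!is.null(elimination) && state$iteration %% elimination$ep == 0L) {
      res <- elimination_phase(state, bounds, elimination, objective)
      state <- res$state
      bounds <- res$bounds
      n_elim_events <- n_elim_events + 1L
    }
    history[it] <- state$best_fitness
  }
  structure(
    list(
      best_x = state$best_x,
      best_fitness = state$best_fitness,
      best_history = history,
      n_evals = state$n_evals,
      n_elimination_events = n_elim_events,
      final_bounds = bounds,
      algorithm = algorithm
    ),
    class = "fox_result"
  )
}

#' Run the FOX optimizer
#'
#' Initializes the population and runs `max_iter` iterations of [fox_step()],
#' recording the best fitness after each iteration.
#'
#' @inheritParams init_population
#' @param seed Integer seed for the run; falls back to `config$seed`. The
#'   whole run is deterministic given the seed.
#' @return An object of class `fox_result`: `best_x`, `best_fitness`,
#'   `best_history` (length `max_iter`, non-increasing), `n_evals`
#'   (`n_agents * (max_iter + 1)`), and `algorithm`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- fox_optimize(sphere, bounds(rep(-100, 5), rep(100, 5)),
#'                     fox_config(n_agents = 10, max_iter = 20), seed = 1)
#' res$best_fitness
#' @export
fox_optimize <- function(objective, bounds, config = fox_config(), seed = NULL) {
  seed <- seed %||% config$seed
  with_local_seed(seed, run_optimizer_loop(objective, bounds, config,
                                           algorithm = "fox"))
}

#' @export
print.fox_result <- function(x, ...) {
  cat(sprintf("<fox_result: %s>\n", x$algorithm))
  cat(sprintf("  best fitness: %.6g after %d evaluations\n",
              x$best_fitness, x$n_evals))
  cat(sprintf("  best x: %s\n",
              paste(signif(utils::head(x$best_x, 6), 4), collapse = ", ")))
  invisible(x)
}
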