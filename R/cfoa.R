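#' @title Contracted fox optimization (CFOA)
#' @description The contracted variant modifies the base optimizer in two
#'   ways: exploration uses Levy-flight steps instead of uniform multipliers
#'   (occasional long jumps that escape local optima), and every `ep`
#'   iterations an elimination phase culls the `et` worst agents, resampling
#'   them uniformly inside a search box that can expand when survivors press
#'   against its edges.
#' @name cfoa
NULL

#' Levy-flight exploration move
#'
#' As [exploration_move()] but the component-wise multiplier is a fresh
#' Levy step vector rather than uniform draws.
#'
#' @inheritParams exploration_move
#' @param params A [levy_params()] object.
#' @return Candidate position vector.
#' @examples
#' set.seed(1)
#' cfoa_exploration_move(c(1, 1), min_t = 0.5, a = 1, levy_params())
#' @export
cfoa_exploration_move <- function(best_x, min_t, a, params = levy_params()) {
  if (min_t < 0 || a < 0) stop("`min_t` and `a` must be non-negative", call. = FALSE)
  best_x * levy_step(length(best_x), params) * (min_t * a)
}

#' Expand the search box where survivors press against it
#'
#' For each dimension, if any surviving agent's coordinate magnitude exceeds
#' `th` percent of that dimension's absolute magnitude
#' (`max(|lower|, |upper|)`), both limits are scaled by `expand_factor`
#' about zero. Other dimensions are unchanged, so the box never shrinks.
#'
#' @param positions Matrix of surviving agent positions (rows = agents).
#' @param bounds The current [bounds()].
#' @param cfg An [elimination_config()] supplying `th` and `expand_factor`.
#' @return A possibly widened [bounds()] object.
#' @examples
#' expand_bounds(matrix(0.9, 1, 1), bounds(-1, 1), elimination_config())
#' @export
expand_bounds <- function(positions, bounds, cfg = elimination_config()) {
  stopifnot(inherits(bounds, "fox_bounds"), inherits(cfg, "elimination_config"))
  if (!is.matrix(positions)) positions <- matrix(positions, nrow = 1L)
  mag <- pmax(abs(bounds$lower), abs(bounds$upper))
  thresh <- (cfg$th / 100) * mag
  over <- apply(abs(positions), 2L, max) > thresh
  if (!any(over)) return(bounds)
  lower <- bounds$lower
  upper <- bounds$upper
  lower[over] <- lower[over] * cfg$expand_factor
  upper[over] <- upper[over] * cfg$expand_factor
  bounds(lower, upper)
}

#' Elimination phase
#'
#' Ranks the population by fitness, replaces the `et` worst agents (highest
#' fitness under the minimization convention) with uniform samples inside the
#' possibly expanded box, re-evaluates them, and refreshes their travel-time
#' rows. Survivors are untouched and the elite best never worsens.
#'
#' @param state A `fox_state`.
#' @param bounds The current [bounds()].
#' @param cfg An [elimination_config()].
#' @param objective The objective function.
#' @return A list with the updated `state` and (possibly expanded) `bounds`.
#' @export
elimination_phase <- function(state, bounds, cfg, objective) {
  stopifnot(inherits(state, "fox_state"))
  n <- length(state$fitness)
  if (cfg$et >= n) {
    stop("`et` must be smaller than the population size", call. = FALSE)
  }
  worst <- order(state$fitness, decreasing = TRUE)[seq_len(cfg$et)]
  survivors <- state$positions[-worst, , drop = FALSE]
  bounds <- expand_bounds(survivors, bounds, cfg)
  fresh <- sample_in_bounds(cfg$et, bounds)
  fresh_fit <- apply(fresh, 1L, objective)
  if (any(!is.finite(fresh_fit))) {
    warning("objective returned non-finite fitness for resampled agent(s); treated as +Inf")
    fresh_fit[!is.finite(fresh_fit)] <- Inf
  }
  state$positions[worst, ] <- fresh
  state$fitness[worst] <- fresh_fit
  state$time_matrix[worst, ] <- matrix(
    pmax(stats::runif(cfg$et * ncol(state$time_matrix)), TIME_FLOOR),
    cfg$et, ncol(state$time_matrix)
  )
  state$n_evals <- state$n_evals + cfg$et
  ibest <- which.min(state$fitness)
  if (state$fitness[ibest] < state$best_fitness) {
    state$best_fitness <- state$fitness[ibest]
    state$best_x <- state$positions[ibest, ]
  }
  list(state = state, bounds = bounds)
}

#' Run the contracted fox optimizer
#'
#' The base loop of [fox_optimize()] with Levy-flight exploration and the
#' periodic elimination phase. Over a run of `max_iter` iterations exactly
#' `floor(max_iter / ep)` elimination events fire; each adds `et` objective
#' evaluations, so `n_evals = n_agents * (max_iter + 1) + events * et`.
#'
#' @inheritParams fox_optimize
#' @param config A [cfoa_config()].
#' @return A `fox_result`; additionally carries `n_elimination_events` and
#'   the `final_bounds` after any expansions.
#' @examples
#' sphere <- function(x) sum(x^2)
#' cfg <- cfoa_config(fox = fox_config(n_agents = 10, max_iter = 20),
#'                    elimination = elimination_config(ep = 10, et = 4))
#' res <- cfoa_optimize(sphere, bounds(rep(-100, 5), rep(100, 5)), cfg, seed = 1)
#' res$n_elimination_events
#' @export
cfoa_optimize <- function(objective, bounds, config = cfoa_config(), seed = NULL) {
  stopifnot(inherits(config, "cfoa_config"))
  seed <- seed %||% config$fox$seed
  with_local_seed(seed, run_optimizer_loop(
    objective, bounds, config$fox,
    levy = config$levy, elimination = config$elimination,
    algorithm = "cfoa"
  ))
}
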