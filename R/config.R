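#' Configuration for the FOX optimizer
#'
#' The fox-hunting metaheuristic balances two phases per agent per iteration:
#' *exploitation* (a pounce toward the incumbent best position, scaled by a
#' jump height derived from simulated sound travel times) and *exploration*
#' (a random walk around the best position). A uniform draw `r` against
#' `r_threshold` selects the phase; inside exploitation a second draw `p`
#' against `p_threshold` selects the jump direction coefficient `c1`
#' (northeast) or `c2` (opposite).
#'
#' @param n_agents Population size (default 60).
#' @param max_iter Number of iterations (default 200).
#' @param c1 Northeast-jump coefficient, in `[0, 0.18]` (default 0.18).
#' @param c2 Opposite-jump coefficient, in `[0.19, 1]` (default 0.82).
#' @param p_threshold Direction threshold for the `p` draw (default 0.18).
#' @param r_threshold Phase threshold for the `r` draw (default 0.5);
#'   exploitation runs when `r >= r_threshold`.
#' @param sound_speed_air Speed of sound in air, m/s; informational constant
#'   (default 343).
#' @param gravity Gravitational acceleration used in the jump-height formula
#'   (default 9.81).
#' @param legacy_a If `TRUE`, use the literal increasing form of the
#'   exploration-control coefficient `a = 2*(it - 1/max_iter)` instead of the
#'   decaying form `2*(1 - it/max_iter)`. Off by default; see [compute_a()].
#' @param seed Optional integer seed attached to the config; used by
#'   [fox_optimize()] when no explicit seed is given.
#'
#' @return An object of class `fox_config`.
#' @examples
#' fox_config(n_agents = 30, max_iter = 100, seed = 1)
#' @export
fox_config <- function(n_agents = 60L, max_iter = 200L,
                       c1 = 0.18, c2 = 0.82,
                       p_threshold = 0.18, r_threshold = 0.5,
                       sound_speed_air = 343, gravity = 9.81,
                       legacy_a = FALSE, seed = NULL) {
  n_agents <- as.integer(n_agents)
  max_iter <- as.integer(max_iter)
  if (n_agents < 2L) stop("`n_agents` must be at least 2", call. = FALSE)
  if (max_iter < 1L) stop("`max_iter` must be at least 1", call. = FALSE)
  if (c1 < 0 || c1 > 0.18) stop("`c1` must lie in [0, 0.18]", call. = FALSE)
  if (c2 < 0.19 || c2 > 1) stop("`c2` must lie in [0.19, 1]", call. = FALSE)
  if (p_threshold <= 0 || p_threshold >= 1) {
    stop("`p_threshold` must lie in (0, 1)", call. = FALSE)
  }
  if (r_threshold <= 0 || r_threshold >= 1) {
    stop("`r_threshold` must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(
      n_agents = n_agents, max_iter = max_iter,
      c1 = c1, c2 = c2,
      p_threshold = p_threshold, r_threshold = r_threshold,
      sound_speed_air = sound_speed_air, gravity = gravity,
      legacy_a = isTRUE(legacy_a),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "fox_config"
  )
}

#' Levy-flight step parameters
#'
#' The contracted variant replaces the uniform exploration multiplier with a
#' heavy-tailed Levy step `w = A / |B|^(1/xi)` where `A ~ N(0, sigma^2)` and
#' `B ~ N(0, 1)`. `sigma` is the standard Mantegna step-scale closed form;
#' see [levy_sigma()].
#'
#' @param xi Levy index in `(0, 2]` (default 3/2).
#' @return An object of class `levy_params` with elements `xi` and `sigma`.
#' @examples
#' levy_params(1.5)$sigma
#' @export
levy_params <- function(xi = 1.5) {
  sigma <- levy_sigma(xi)
  structure(list(xi = xi, sigma = sigma), class = "levy_params")
}

#' Elimination-phase configuration
#'
#' Every `ep` iterations the `et` worst agents (highest fitness, minimization
#' convention) are culled and resampled uniformly inside the current — possibly
#' expanded — search box. A dimension's box is widened by `expand_factor`
#' (about zero) whenever a surviving agent sits beyond `th` percent of that
#' dimension's absolute magnitude; see [expand_bounds()].
#'
#' @param ep Elimination period in iterations (default 40).
#' @param et Number of agents eliminated per event (default 30).
#' @param th Expansion trigger threshold as a percentage of the solution
#'   space's absolute magnitude, in `(0, 100]` (default 60).
#' @param expand_factor Multiplicative widening applied to a triggered
#'   dimension's limits, `> 1` (default 1.25).
#' @return An object of class `elimination_config`.
#' @export
elimination_config <- function(ep = 40L, et = 30L, th = 60, expand_factor = 1.25) {
  ep <- as.integer(ep)
  et <- as.integer(et)
  if (ep < 1L) stop("`ep` must be at least 1", call. = FALSE)
  if (et < 1L) stop("`et` must be at least 1", call. = FALSE)
  if (th <= 0 || th > 100) stop("`th` must lie in (0, 100]", call. = FALSE)
  if (expand_factor <= 1) stop("`expand_factor` must exceed 1", call. = FALSE)
  structure(
    list(ep = ep, et = et, th = th, expand_factor = expand_factor),
    class = "elimination_config"
  )
}

#' Configuration for the contracted fox optimizer (CFOA)
#'
#' Bundles the base FOX configuration with the Levy-flight exploration
#' parameters and the elimination-phase schedule.
#'
#' @param fox A [fox_config()].
#' @param levy A [levy_params()].
#' @param elimination An [elimination_config()].
#' @return An object of class `cfoa_config`.
#' @examples
#' cfg <- cfoa_config(fox = fox_config(seed = 1))
#' @export
cfoa_config <- function(fox = fox_config(), levy = levy_params(),
                        elimination = elimination_config()) {
  stopifnot(inherits(fox, "fox_config"))
  stopifnot(inherits(levy, "levy_params"))
  stopifnot(inherits(elimination, "elimination_config"))
  if (elimination$et >= fox$n_agents) {
    stop("`et` must be smaller than the population size", call. = FALSE)
  }
  structure(
    list(fox = fox, levy = levy, elimination = elimination),
    class = "cfoa_config"
  )
}

#' Read a CFOA configuration from a YAML or JSON file
#'
#' The file mirrors the structure of [cfoa_config()]: top-level keys `fox`,
#' `levy` and `elimination`, each holding the corresponding constructor's
#' arguments. Unknown keys are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [cfoa_config()] object.
#' @export
read_cfoa_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known_top <- c("fox", "levy", "elimination")
  extra <- setdiff(names(raw), known_top)
  if (length(extra)) {
    stop("unknown config keys: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  check_args <- function(given, fn, label) {
    ok <- setdiff(names(formals(fn)), "...")
    bad <- setdiff(names(given), ok)
    if (length(bad)) {
      stop(sprintf("unknown %s config keys: %s", label, paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    given
  }
  fox <- do.call(fox_config, check_args(raw$fox %||% list(), fox_config, "fox"))
  levy <- do.call(levy_params, check_args(raw$levy %||% list(), levy_params, "levy"))
  elim <- do.call(elimination_config,
                  check_args(raw$elimination %||% list(), elimination_config,
                             "elimination"))
  cfoa_config(fox = fox, levy = levy, elimination = elim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run expr with a locally seeded RNG stream, restoring the caller's stream.
# seed = NULL leaves the global stream untouched (still consumed).
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}
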