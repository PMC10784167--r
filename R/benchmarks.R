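#' Classical benchmark objective registry
#'
#' A suite of analytic test functions with documented boxes and known minima,
#' used to exercise the optimizers: sphere, Rosenbrock, Rastrigin, Ackley,
#' Griewank, Schwefel 2.21 (max modulus), the Levy surface, and Zakharov.
#' All are minimization problems with minimum value 0.
#'
#' @param dim Dimension at which to instantiate every function (default 10).
#' @return Named list of `benchmark_function` objects, each with `name`,
#'   `dim`, `bounds`, `evaluate` and `known_minimum`.
#' @examples
#' reg <- benchmark_registry(10)
#' reg$sphere$evaluate(rep(0, 10))
#' @export
benchmark_registry <- function(dim = 10L) {
  dim <- as.integer(dim)
  mk <- function(name, lo, hi, f, argmin) {
    structure(
      list(
        name = name, dim = dim,
        bounds = bounds(rep(lo, dim), rep(hi, dim)),
        evaluate = f, known_minimum = 0,
        argmin = rep(argmin, dim)
      ),
      class = "benchmark_function"
    )
  }
  list(
    sphere = mk("sphere", -100, 100, function(x) sum(x^2), 0),
    rosenbrock = mk("rosenbrock", -30, 30, function(x) {
      n <- length(x)
      sum(100 * (x[-1] - x[-n]^2)^2 + (1 - x[-n])^2)
    }, 1),
    rastrigin = mk("rastrigin", -5.12, 5.12, function(x) {
      sum(x^2 - 10 * cos(2 * pi * x)) + 10 * length(x)
    }, 0),
    ackley = mk("ackley", -32, 32, function(x) {
      n <- length(x)
      -20 * exp(-0.2 * sqrt(sum(x^2) / n)) -
        exp(sum(cos(2 * pi * x)) / n) + 20 + exp(1)
    }, 0),
    griewank = mk("griewank", -600, 600, function(x) {
      sum(x^2) / 4000 - prod(cos(x / sqrt(seq_along(x)))) + 1
    }, 0),
    schwefel_2_21 = mk("schwefel_2_21", -100, 100, function(x) max(abs(x)), 0),
    levy_surface = mk("levy_surface", -10, 10, function(x) {
      w <- 1 + (x - 1) / 4
      n <- length(x)
      sin(pi * w[1])^2 +
        sum((w[-n] - 1)^2 * (1 + 10 * sin(pi * w[-n] + 1)^2)) +
        (w[n] - 1)^2 * (1 + sin(2 * pi * w[n])^2)
    }, 1),
    zakharov = mk("zakharov", -5, 10, function(x) {
      s <- sum(0.5 * seq_along(x) * x)
      sum(x^2) + s^2 + s^4
    }, 0)
  )
}

#' Random-search baseline
#'
#' Draws the same evaluation budget as a FOX run with the given config
#' (`n_agents * (max_iter + 1)` uniform samples in the box) and tracks the
#' running best per iteration-sized block. This is the built-in comparator
#' for the population optimizers.
#'
#' @inheritParams fox_optimize
#' @return A `fox_result` with `algorithm = "random_search"`.
#' @export
random_search <- function(objective, bounds, config = fox_config(), seed = NULL) {
  seed <- seed %||% config$seed
  with_local_seed(seed, {
    n <- config$n_agents
    best_f <- Inf
    best_x <- rep(NA_real_, bounds$dim)
    history <- numeric(config$max_iter)
    for (block in 0:config$max_iter) {
      pts <- sample_in_bounds(n, bounds)
      f <- apply(pts, 1L, objective)
      f[!is.finite(f)] <- Inf
      i <- which.min(f)
      if (f[i] < best_f) {
        best_f <- f[i]
        best_x <- pts[i, ]
      }
      if (block >= 1L) history[block] <- best_f
    }
    structure(
      list(
        best_x = best_x, best_fitness = best_f, best_history = history,
        n_evals = n * (config$max_iter + 1L),
        algorithm = "random_search"
      ),
      class = "fox_result"
    )
  })
}

#' Repeated seeded trials of an optimizer on a benchmark
#'
#' Runs the optimizer with seeds `base_seed .. base_seed + n_runs - 1` and
#' aggregates the per-run final best fitnesses into Best / Mean / StD
#' summary statistics (sample standard deviation; 0 by convention for a
#' single run). A run that errors is recorded as missing with a warning and
#' excluded from the aggregates.
#'
#' @param algo An optimizer callable `function(objective, bounds, seed)`
#'   returning a `fox_result`, or one of the strings `"fox"`, `"cfoa"`,
#'   `"random_search"` (run with default configs).
#' @param fn A `benchmark_function` from [benchmark_registry()].
#' @param n_runs Number of repeats (default 25).
#' @param base_seed First seed (default 1).
#' @param algo_name Label for reports; inferred when `algo` is a string.
#' @return An object of class `trial_stats`: `function_name`, `algo_name`,
#'   `n_runs`, `best`, `mean`, `std`, `per_run_finals`.
#' @examples
#' reg <- benchmark_registry(5)
#' algo <- function(obj, b, seed) {
#'   fox_optimize(obj, b, fox_config(n_agents = 10, max_iter = 20), seed)
#' }
#' run_trials(algo, reg$sphere, n_runs = 3, base_seed = 1, algo_name = "fox")
#' @export
run_trials <- function(algo, fn, n_runs = 25L, base_seed = 1L, algo_name = NULL) {
  stopifnot(inherits(fn, "benchmark_function"))
  n_runs <- as.integer(n_runs)
  if (n_runs < 1L) stop("`n_runs` must be at least 1", call. = FALSE)
  if (is.character(algo)) {
    algo_name <- algo_name %||% algo
    algo <- switch(algo,
      fox = function(obj, b, seed) fox_optimize(obj, b, fox_config(), seed),
      cfoa = function(obj, b, seed) cfoa_optimize(obj, b, cfoa_config(), seed),
      random_search = function(obj, b, seed) random_search(obj, b, fox_config(), seed),
      stop("unknown algorithm name: ", algo, call. = FALSE)
    )
  }
  algo_name <- algo_name %||% "custom"
  finals <- rep(NA_real_, n_runs)
  for (i in seq_len(n_runs)) {
    seed <- base_seed + i - 1L
    res <- tryCatch(algo(fn$evaluate, fn$bounds, seed), error = function(e) {
      warning(sprintf("run with seed %d failed: %s", seed, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) finals[i] <- res$best_fitness
  }
  ok <- finals[!is.na(finals)]
  std <- if (length(ok) > 1L) stats::sd(ok) else 0
  structure(
    list(
      function_name = fn$name, algo_name = algo_name, n_runs = n_runs,
      best = min(ok), mean = mean(ok), std = std,
      per_run_finals = finals
    ),
    class = "trial_stats"
  )
}

#' @export
print.trial_stats <- function(x, ...) {
  cat(sprintf("<trial_stats> %s on %s (%d runs)\n",
              x$algo_name, x$function_name, x$n_runs))
  cat(sprintf("  Best %.6g | Mean %.6g | StD %.6g\n", x$best, x$mean, x$std))
  invisible(x)
}

#' Tabulate trial statistics in the Best/Mean/StD layout
#'
#' Produces a tibble with one row per (function, indicator) pair and one
#' value column per algorithm — the conventional comparison-table layout for
#' metaheuristic benchmarks. Optionally writes it as CSV.
#'
#' @param stats A list of `trial_stats` objects (or a single one).
#' @param file Optional CSV path to write the table to.
#' @return A tibble with columns `fn`, `indicator`, then one per algorithm.
#' @examples
#' reg <- benchmark_registry(5)
#' algo <- function(obj, b, seed) {
#'   fox_optimize(obj, b, fox_config(n_agents = 10, max_iter = 10), seed)
#' }
#' st <- run_trials(algo, reg$sphere, n_runs = 2, algo_name = "fox")
#' stats_table(list(st))
#' @export
stats_table <- function(stats, file = NULL) {
  if (inherits(stats, "trial_stats")) stats <- list(stats)
  if (length(stats) == 0L) {
    out <- tibble::tibble(fn = character(), indicator = character())
  } else {
    fns <- unique(vapply(stats, `[[`, "", "function_name"))
    algos <- unique(vapply(stats, `[[`, "", "algo_name"))
    rows <- expand.grid(indicator = c("Best", "Mean", "StD"), fn = fns,
                        stringsAsFactors = FALSE)[, c("fn", "indicator")]
    rows <- rows[order(match(rows$fn, fns)), ]
    out <- tibble::as_tibble(rows)
    for (a in algos) {
      vals <- rep(NA_real_, nrow(out))
      for (s in stats) {
        if (s$algo_name != a) next
        i <- which(out$fn == s$function_name)
        vals[i] <- c(s$best, s$mean, s$std)[match(out$indicator[i],
                                                  c("Best", "Mean", "StD"))]
      }
      out[[a]] <- vals
    }
  }
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE)
  }
  out
}
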