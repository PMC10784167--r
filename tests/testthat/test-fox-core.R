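test_that("bounds validate their limits", {
  expect_error(bounds(c(0, 0), c(0, 0)), "invalid bounds")
  expect_error(bounds(1, -1), "invalid bounds")
  expect_error(bounds(c(0, 1), 2), "same length")
  b <- bounds(c(-1, -1), c(1, 1))
  expect_equal(b$dim, 2L)
})

test_that("clamp_to_bounds projects onto the box", {
  b <- bounds(c(-1, -1), c(1, 1))
  expect_equal(clamp_to_bounds(c(5, 0.5), b), c(1, 0.5))
  expect_equal(clamp_to_bounds(c(-3, 0.5), b), c(-1, 0.5))
  x <- c(0.2, -0.7)
  expect_identical(clamp_to_bounds(x, b), x)
})

test_that("sound-speed, distance and jump arithmetic follow the model", {
  expect_equal(compute_sound_speed(343, 1), 343)
  expect_equal(compute_sound_speed(c(10, 20), c(0.5, 0.5)), c(20, 40))
  expect_equal(compute_sound_speed(c(0, 0), c(0.3, 0.9)), c(0, 0))
  # zero time is floored, not a fault
  expect_true(is.finite(compute_sound_speed(1, 0)))

  d <- compute_distances(c(10, 20), c(0.5, 0.5))
  expect_equal(d$dist_s_t, c(5, 10))
  expect_equal(d$dist_fox_prey, c(2.5, 5))
  expect_equal(compute_distances(c(0, 0), c(1, 1))$dist_fox_prey, c(0, 0))
  expect_error(compute_distances(1:2, 1:3), "same length")

  expect_equal(compute_jump(c(1, 1)), 0.5 * 9.81 * 0.25)
  expect_equal(compute_jump(c(0, 0)), 0)
  expect_equal(compute_jump(c(0.2, 0.4)), 0.1103625)
  expect_error(compute_jump(numeric(0)), "non-empty")
})

test_that("the distance chain algebraically collapses to half the best position", {
  # speed = best/time, dist = speed*time, fox-prey = half: the composition
  # must return 0.5 * best_x exactly for any positive times
  set.seed(1)
  for (i in 1:20) {
    best_x <- rnorm(5, sd = 10)
    time_row <- runif(5, 0.01, 1)
    d <- compute_distances(compute_sound_speed(best_x, time_row), time_row)
    expect_equal(d$dist_fox_prey, 0.5 * best_x)
  }
})

test_that("exploitation move applies the direction coefficients", {
  cfg <- fox_config()
  expect_equal(exploitation_move(c(2, 2), 1, p = 0.5, cfg), c(0.36, 0.36))
  expect_equal(exploitation_move(c(2, 2), 1, p = 0.1, cfg), c(1.64, 1.64))
  expect_equal(exploitation_move(c(0, 0), 3, p = 0.9, cfg), c(0, 0))
  expect_error(exploitation_move(c(1, 1), 1, p = 2, cfg), "\\[0, 1\\]")
})

test_that("minimum mean travel time and the decay coefficient", {
  expect_equal(compute_min_t(rbind(c(0.2, 0.4), c(0.6, 0.8))), 0.3)
  expect_equal(compute_min_t(matrix(0.5, 3, 4)), 0.5)
  expect_equal(compute_min_t(matrix(c(1, 0), 1, 2)), 0.5)
  expect_error(compute_min_t(matrix(nrow = 0, ncol = 2)), "non-empty")

  expect_equal(compute_a(200, 200), 0)
  expect_equal(compute_a(100, 200), 1)
  expect_equal(compute_a(50, 200), 1.5)
  expect_error(compute_a(0, 200), "must lie")
  # the literal legacy form increases with it
  expect_equal(compute_a(50, 200, legacy = TRUE), 2 * (50 - 1 / 200))
  expect_gt(compute_a(100, 200, legacy = TRUE), compute_a(50, 200, legacy = TRUE))
})

test_that("exploration move scales the best position by bounded randomness", {
  expect_equal(exploration_move(c(0, 0), 1, 1), c(0, 0))
  set.seed(3)
  expect_equal(exploration_move(c(1, 2, 3), min_t = 1, a = 0), c(0, 0, 0))
  set.seed(4)
  out <- exploration_move(c(1, 1), min_t = 1, a = 1)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("population initialization samples inside bounds deterministically", {
  b <- bounds(rep(-1, 2), rep(1, 2))
  cfg <- fox_config(n_agents = 60, max_iter = 10)
  sphere <- function(x) sum(x^2)
  set.seed(11)
  st <- init_population(sphere, b, cfg)
  expect_true(all(st$positions >= -1 & st$positions <= 1))
  expect_equal(dim(st$positions), c(60L, 2L))
  expect_equal(st$best_fitness, min(st$fitness))
  expect_true(all(st$time_matrix >= 0 & st$time_matrix <= 1))
  expect_equal(st$n_evals, 60L)
  set.seed(11)
  st2 <- init_population(sphere, b, cfg)
  expect_identical(st$positions, st2$positions)
})

test_that("one step keeps the elite, counts evaluations, and is seed-reproducible", {
  b <- bounds(rep(-5, 4), rep(5, 4))
  cfg <- fox_config(n_agents = 20, max_iter = 10)
  sphere <- function(x) sum(x^2)
  set.seed(2)
  st <- init_population(sphere, b, cfg)
  set.seed(5)
  st1 <- fox_step(st, sphere, b, cfg)
  expect_lte(st1$best_fitness, st$best_fitness)
  expect_equal(st1$n_evals - st$n_evals, 20L)
  expect_equal(st1$iteration, 1L)
  expect_true(all(st1$positions >= -5 & st1$positions <= 5))
  set.seed(5)
  st1b <- fox_step(st, sphere, b, cfg)
  expect_identical(st1, st1b)
})

test_that("a non-finite objective keeps the previous fitness with a warning", {
  b <- bounds(rep(-1, 2), rep(1, 2))
  cfg <- fox_config(n_agents = 5, max_iter = 3)
  bad <- function(x) NaN
  set.seed(8)
  st <- init_population(function(x) sum(x^2), b, cfg)
  expect_warning(st1 <- fox_step(st, bad, b, cfg), "non-finite")
  expect_identical(st1$fitness, st$fitness)
  expect_true(all(is.finite(st1$fitness)))
})

test_that("a full run is elitist, budget-exact and deterministic", {
  sphere <- function(x) sum(x^2)
  b <- bounds(rep(-100, 10), rep(100, 10))
  cfg <- fox_config(n_agents = 20, max_iter = 40)
  res <- fox_optimize(sphere, b, cfg, seed = 1)
  expect_length(res$best_history, 40L)
  expect_true(all(diff(res$best_history) <= 0))
  expect_equal(res$n_evals, 20L * 41L)
  expect_lt(res$best_fitness, res$best_history[1])
  res2 <- fox_optimize(sphere, b, cfg, seed = 1)
  expect_identical(res, res2)
  res3 <- fox_optimize(sphere, b, cfg, seed = 2)
  expect_false(identical(res$best_history, res3$best_history))
})

test_that("all-exploitation with a zero best collapses the population", {
  # with r_threshold ~ 0 every agent exploits; moves scale 0.5 * best_x,
  # so a zero best collapses everyone to the origin in one step
  b <- bounds(rep(-1, 3), rep(1, 3))
  cfg <- fox_config(n_agents = 6, max_iter = 5, r_threshold = 1e-9)
  sphere <- function(x) sum(x^2)
  set.seed(9)
  st <- init_population(sphere, b, cfg)
  st$best_x <- rep(0, 3)
  st1 <- fox_step(st, sphere, b, cfg)
  expect_true(all(st1$positions == 0))
})

test_that("fox beats random search on the sphere at an equal budget", {
  sphere <- function(x) sum(x^2)
  b <- bounds(rep(-100, 10), rep(100, 10))
  cfg <- fox_config(n_agents = 20, max_iter = 40)
  finals_fox <- vapply(1:5, function(s)
    fox_optimize(sphere, b, cfg, seed = s)$best_fitness, 0)
  finals_rs <- vapply(1:5, function(s)
    random_search(sphere, b, cfg, seed = s)$best_fitness, 0)
  expect_lt(median(finals_fox), median(finals_rs))
})

test_that("config validation enforces the documented coefficient ranges", {
  expect_error(fox_config(c1 = 0.3), "c1")
  expect_error(fox_config(c2 = 0.1), "c2")
  expect_error(fox_config(n_agents = 1), "at least 2")
  expect_error(fox_config(r_threshold = 0), "r_threshold")
})
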