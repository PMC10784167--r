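test_that("the Levy step scale has its analytic values", {
  expect_equal(levy_sigma(1), 1)
  expect_equal(levy_sigma(1.5), 0.696575, tolerance = 1e-4)
  expect_error(levy_sigma(0), "in \\(0, 2\\]")
  expect_error(levy_sigma(2.5), "in \\(0, 2\\]")
})

test_that("Levy steps are reproducible and heavy-tailed", {
  p <- levy_params(1.5)
  set.seed(1)
  w1 <- levy_step(10, p)
  set.seed(1)
  w2 <- levy_step(10, p)
  expect_identical(w1, w2)
  expect_true(all(is.finite(w1)))

  # tail index of |w| at xi = 1.5 estimated from a large sample
  set.seed(42)
  w <- abs(levy_step(2e5, p))
  expect_gt(hill_estimator(w, 1000L), 1.3)
  expect_lt(hill_estimator(w, 1000L), 1.7)
})

test_that("xi = 2 steps have far lighter tails than xi = 1.5", {
  # extreme exceedances are far more frequent at the heavier index; the
  # tail survival drops from t^-1.5 to t^-2
  set.seed(7)
  n <- 5e4
  exceed15 <- mean(abs(levy_step(n, levy_params(1.5))) > 20)
  set.seed(7)
  exceed20 <- mean(abs(levy_step(n, levy_params(2))) > 20)
  expect_gt(exceed15, 3 * exceed20)
})

test_that("the sample variance of xi = 1.5 steps diverges while the median stays put", {
  # with tail index 1.5 the variance is infinite: the sample variance grows
  # like n^(1/3) (expected factor ~4.6 from 1e4 to 1e6 draws) while the
  # median is stable
  set.seed(13)
  w_small <- abs(levy_step(1e4, levy_params(1.5)))
  set.seed(13)
  w_big <- abs(levy_step(1e6, levy_params(1.5)))
  expect_lt(abs(median(w_big) - median(w_small)) / median(w_small), 0.25)
  expect_gt(var(w_big) / var(w_small), 2)
})

test_that("Levy exploration moves share the zero and stub behavior of the base walk", {
  p <- levy_params()
  expect_equal(cfoa_exploration_move(c(0, 0), 1, 1, p), c(0, 0))
  set.seed(1)
  expect_equal(cfoa_exploration_move(c(1, 2), 1, 0, p), c(0, 0))
  # with the Levy stream replaced by ones the move is best_x * min_t * a
  best_x <- c(2, -3)
  expect_equal(best_x * c(1, 1) * (0.5 * 1.2), best_x * 0.6)
})

test_that("bound expansion triggers per dimension at the magnitude threshold", {
  cfg <- elimination_config(th = 60, expand_factor = 1.25)
  b <- bounds(c(-1, -1), c(1, 1))
  # nothing beyond 60% of magnitude: unchanged
  same <- expand_bounds(rbind(c(0.5, 0.2)), b, cfg)
  expect_equal(same$lower, b$lower)
  expect_equal(same$upper, b$upper)
  # one coordinate at 0.9: only that dimension expands
  ex <- expand_bounds(rbind(c(0.9, 0.1)), b, cfg)
  expect_equal(ex$lower, c(-1.25, -1))
  expect_equal(ex$upper, c(1.25, 1))
  # all-zero survivors: unchanged
  z <- expand_bounds(matrix(0, 4, 2), b, cfg)
  expect_equal(z$upper, b$upper)
})

test_that("elimination replaces exactly the worst agents and keeps the best", {
  sphere <- function(x) sum(x^2)
  b <- bounds(rep(-1, 2), rep(1, 2))
  cfg <- fox_config(n_agents = 4, max_iter = 10)
  set.seed(21)
  st <- init_population(sphere, b, cfg)
  st$fitness <- c(1, 9, 2, 8)
  st$best_fitness <- 1
  st$best_x <- st$positions[1, ]
  old_pos <- st$positions
  ecfg <- elimination_config(ep = 1, et = 2)
  set.seed(22)
  out <- elimination_phase(st, b, ecfg, sphere)
  # agents with fitness 9 and 8 replaced; 1 and 2 preserved
  expect_identical(out$state$positions[1, ], old_pos[1, ])
  expect_identical(out$state$positions[3, ], old_pos[3, ])
  expect_false(identical(out$state$positions[2, ], old_pos[2, ]))
  expect_false(identical(out$state$positions[4, ], old_pos[4, ]))
  expect_lte(out$state$best_fitness, 1)
  expect_equal(out$state$n_evals - st$n_evals, 2L)
  expect_error(elimination_phase(st, b, elimination_config(et = 4), sphere),
               "smaller than the population")
})

test_that("a CFOA run fires the scheduled eliminations and stays elitist", {
  sphere <- function(x) sum(x^2)
  b <- bounds(rep(-100, 5), rep(100, 5))
  cfg <- cfoa_config(fox = fox_config(n_agents = 12, max_iter = 50),
                     elimination = elimination_config(ep = 10, et = 5))
  res <- cfoa_optimize(sphere, b, cfg, seed = 3)
  expect_equal(res$n_elimination_events, 5L)
  expect_true(all(diff(res$best_history) <= 0))
  expect_equal(res$n_evals, 12L * 51L + 5L * 5L)
  # bounds never shrink
  expect_true(all(res$final_bounds$upper >= 100 - 1e-12))
  res2 <- cfoa_optimize(sphere, b, cfg, seed = 3)
  expect_identical(res, res2)
})

test_that("with ep beyond the horizon CFOA is FOX-with-Levy exactly", {
  sphere <- function(x) sum(x^2)
  b <- bounds(rep(-10, 3), rep(10, 3))
  fox <- fox_config(n_agents = 8, max_iter = 20)
  with_elim <- cfoa_config(fox = fox,
                           elimination = elimination_config(ep = 21, et = 3))
  r1 <- cfoa_optimize(sphere, b, with_elim, seed = 5)
  expect_equal(r1$n_elimination_events, 0L)
  expect_equal(r1$n_evals, 8L * 21L)
  # a second no-elimination schedule gives the identical trajectory
  with_elim2 <- cfoa_config(fox = fox,
                            elimination = elimination_config(ep = 1000, et = 3))
  r2 <- cfoa_optimize(sphere, b, with_elim2, seed = 5)
  expect_identical(r1$best_history, r2$best_history)
})

test_that("config constructors reject inconsistent elimination settings", {
  expect_error(cfoa_config(fox = fox_config(n_agents = 10),
                           elimination = elimination_config(et = 30)),
               "smaller than the population")
  expect_error(elimination_config(th = 0), "th")
  expect_error(elimination_config(expand_factor = 1), "expand_factor")
})

test_that("a config file round-trips through YAML and rejects unknown keys", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "fox:", "  n_agents: 12", "  max_iter: 30",
    "levy:", "  xi: 1.5",
    "elimination:", "  ep: 10", "  et: 5"
  ), f)
  cfg <- read_cfoa_config(f)
  expect_equal(cfg$fox$n_agents, 12L)
  expect_equal(cfg$elimination$ep, 10L)
  writeLines(c("fox:", "  n_agents: 12", "bogus: 1"), f)
  expect_error(read_cfoa_config(f), "unknown config keys")
  writeLines(c("fox:", "  n_agents: 12", "  warp: 9"), f)
  expect_error(read_cfoa_config(f), "unknown fox config keys")
})
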