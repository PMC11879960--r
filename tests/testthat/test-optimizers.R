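fast_cfg <- function(...) optimizer_config(population = 30, iterations = 100, ...)

test_that("continuous optimizers recover a concave 1-D maximum", {
  sp <- oneD_space()
  obj <- oneD_objective()
  for (alg in c("ga", "pso", "sa", "de", "abc")) {
    res <- run_optimizer(alg, obj, sp, optimizer_config(seed = 2))
    expect_lt(abs(res$best_schedule$t_session - 7.3), 0.05, label = alg)
  }
})

test_that("every algorithm is bit-reproducible for a fixed seed", {
  sp_c <- decision_space()
  sp_d <- toy_space()
  obj <- toy_objective()
  for (alg in c("ga", "pso", "sa", "de", "abc")) {
    a <- run_optimizer(alg, obj, sp_c, optimizer_config(20, 15, seed = 7))
    b <- run_optimizer(alg, obj, sp_c, optimizer_config(20, 15, seed = 7))
    expect_identical(a, b, label = alg)
  }
  a <- run_aco(obj, sp_d, optimizer_config(20, 15, seed = 7))
  b <- run_aco(obj, sp_d, optimizer_config(20, 15, seed = 7))
  expect_identical(a, b)
})

test_that("frozen particle swarm dynamics never move from the initial population", {
  res <- run_pso(oneD_objective(), oneD_space(),
                 optimizer_config(20, 30, seed = 5,
                                  pso = list(w = 0, c1 = 0, c2 = 0)))
  expect_true(all(res$trajectory == res$trajectory[1]))
  expect_equal(res$best_fitness, res$trajectory[1])
})

test_that("ant colony optimization requires a discretized space", {
  expect_error(run_aco(toy_objective(), decision_space()), "discretized")
})

test_that("a fully frozen grid returns its unique schedule at iteration 1", {
  sp <- decision_space(
    t_bounds = c(1, 1), n_bounds = c(3L, 3L), t_max_weekly = 10,
    levels = c(
      list(t_session = 1, n_sessions = 3, a_aerobic = 1),
      stats::setNames(rep(list(0), 4), SCHEDULE_COORDS[4:7]),
      list(i_low = 0, i_moderate = 0, i_vigorous = 1)
    )
  )
  res <- run_aco(toy_objective(), sp, optimizer_config(10, 5, seed = 1))
  expect_equal(res$best_schedule$t_session, 1)
  expect_equal(res$best_schedule$n_sessions, 3L)
  expect_equal(unname(res$best_schedule$activity_mix), c(1, 0, 0, 0, 0))
  expect_true(all(res$trajectory == res$trajectory[1]))
})

test_that("with full evaporation and constant fitness, ant sampling stays uniform", {
  # rho = 1 resets pheromone each iteration and a constant-zero fitness
  # deposits nothing, so level selection stays a uniform multinomial
  sp <- decision_space(
    t_bounds = c(0, 3), n_bounds = c(1L, 1L), t_max_weekly = 3,
    levels = c(
      list(t_session = c(0, 1, 2, 3), n_sessions = 1),
      stats::setNames(rep(list(0.5), 8), SCHEDULE_COORDS[3:10])
    )
  )
  counts <- new.env()
  counts$tab <- numeric(4)
  obj <- function(D) {
    idx <- D[, "t_session"] + 1
    for (i in idx) counts$tab[i] <- counts$tab[i] + 1
    rep(0, nrow(D))
  }
  run_aco(obj, sp, optimizer_config(population = 100, iterations = 100,
                                    seed = 3, aco = list(rho = 1)))
  draws <- sum(counts$tab)
  expect_equal(draws, 100 * 100)
  sigma <- sqrt(draws * 0.25 * 0.75)
  expect_true(all(abs(counts$tab - draws / 4) < 3 * sigma))
})

test_that("the Metropolis rule and geometric cooling match their closed forms", {
  expect_equal(sa_accept(0, 1), 1)
  expect_equal(sa_accept(-2, 1), 1)
  expect_equal(sa_accept(1, 1), exp(-1))
  expect_equal(sa_accept(2, 4), exp(-0.5))
  expect_error(sa_accept(1, 0), "temperature")
  expect_equal(sa_temperature(100, 0.95, 10), 100 * 0.95^10)
  expect_error(sa_temperature(100, 1, 10), "gamma")
})

test_that("differential-evolution primitives match the stated algebra", {
  expect_identical(de_mutate(c(1, 2), c(3, 4), c(1, 1), f = 0), c(1, 2))
  expect_equal(de_mutate(c(1, 2), c(3, 4), c(1, 1), f = 0.5), c(2, 3.5))
  # swapping the difference pair negates the perturbation about x_r1
  x1 <- c(2, 5); x2 <- c(1, 7); x3 <- c(4, 0)
  expect_equal(de_mutate(x1, x2, x3, 0.8) - x1,
               -(de_mutate(x1, x3, x2, 0.8) - x1))

  expect_equal(de_crossover(1:5, 6:10, cr = 1, seed = 1), 6:10)
  tr <- de_crossover(rep(0, 8), rep(1, 8), cr = 0, seed = 2)
  expect_equal(sum(tr), 1) # only the guaranteed donor component
  expect_error(de_crossover(1:3, 4:6, cr = 1.5), "cr")
})

test_that("binomial crossover takes donor components at the requested rate", {
  set.seed(8)
  d <- 100
  frac <- mean(vapply(1:100, function(i) {
    mean(de_crossover(rep(0, d), rep(1, d), cr = 0.7))
  }, numeric(1)))
  # expected donor fraction is cr + (1 - cr)/d = 0.703 at d = 100
  expect_lt(abs(frac - 0.7), 0.02)
})

test_that("differential evolution refuses populations too small for distinct indices", {
  expect_error(run_de(oneD_objective(), oneD_space(),
                      optimizer_config(population = 3, iterations = 5)),
               "distinct")
})

test_that("onlooker selection probabilities are a normalized fitness transform", {
  fit <- c(0.2, 0.5, 0.3)
  p <- peopt:::abc_selection_probs(fit)
  expect_equal(sum(p), 1)
  shifted <- fit - min(fit) + 1e-12
  expect_equal(p, shifted / sum(shifted))
})

test_that("bee-colony sources exceeding the trial limit are re-initialized by scouts", {
  # a constant objective never improves, so trial counters only grow and
  # every source must eventually be abandoned
  obj <- function(D) rep(0.5, nrow(D))
  res <- run_abc(obj, decision_space(),
                 optimizer_config(population = 10, iterations = 10, seed = 4,
                                  debug = TRUE, abc = list(limit = 1)))
  n_scouts <- sum(lengths(res$debug$scouts))
  expect_gt(n_scouts, 0)
  # a re-initialized source restarts with a reset trial counter
  first_scout_iter <- which(lengths(res$debug$scouts) > 0)[1]
  s <- res$debug$scouts[[first_scout_iter]][1]
  expect_lte(res$debug$trials[[first_scout_iter]][s],
             1 + res$debug$trials[[max(1, first_scout_iter - 1)]][s])
})

test_that("trajectories are non-decreasing and budgets exact across algorithms and seeds", {
  sp <- toy_space()
  obj <- toy_objective()
  for (alg in c("ga", "pso", "aco", "sa", "de", "abc")) {
    for (seed in 1:3) {
      cfg <- optimizer_config(population = 16, iterations = 25, seed = seed,
                              cache = TRUE)
      res <- run_optimizer(alg, obj, sp, cfg)
      expect_true(all(diff(res$trajectory) >= 0), label = paste(alg, seed))
      expect_length(res$trajectory, 25)
      expect_equal(res$best_fitness, res$trajectory[25])
      expect_lte(res$evaluations, 16 * 25 + 16)
    }
  }
})

test_that("each metaheuristic reaches the exhaustive-search optimum on the toy grid", {
  sp <- toy_space()
  obj <- toy_objective()
  opt <- exhaustive_oracle(obj, sp)$best_fitness
  for (alg in c("ga", "pso", "aco", "sa", "de", "abc")) {
    for (seed in 4:6) {
      res <- run_optimizer(alg, obj, sp,
                           optimizer_config(30, 100, seed = seed, cache = TRUE))
      expect_lte(res$best_fitness, opt + 1e-12)
      expect_equal(res$best_fitness, opt, tolerance = 1e-12,
                   label = paste(alg, seed))
    }
  }
})

test_that("grid caching does not change optimization results", {
  sp <- toy_space()
  obj <- toy_objective()
  a <- run_ga(obj, sp, optimizer_config(20, 30, seed = 9, cache = TRUE))
  b <- run_ga(obj, sp, optimizer_config(20, 30, seed = 9, cache = FALSE))
  expect_equal(a$best_fitness, b$best_fitness)
  expect_equal(a$trajectory, b$trajectory)
  expect_equal(a$best_schedule, b$best_schedule)
})
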