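# Six from-scratch metaheuristics over the schedule decision space, all
# maximizing a shared vectorized objective under one evaluation-budget
# convention: `population` candidate evaluations to initialize plus
# `population` per iteration, so every algorithm consumes at most
# population * iterations + population objective evaluations.

#' Optimizer configuration
#'
#' Shared budget settings plus per-algorithm hyperparameters. Unspecified
#' hyperparameters take the documented defaults.
#'
#' @param population Candidate evaluations per iteration (default 30). The
#'   bee colony splits this into `population / 2` food sources with an
#'   employed and an onlooker evaluation each; simulated annealing runs
#'   `population` independent chains unless `sa$chains` overrides it.
#' @param iterations Iteration count (default 200).
#' @param seed RNG seed; every run is bit-reproducible for a fixed seed.
#' @param cache If `TRUE` and the space is fully discretized, objective
#'   values are cached per grid point (repeat visits are lookups; the
#'   reported evaluation count is unaffected).
#' @param debug If `TRUE`, algorithms attach diagnostic per-iteration state
#'   (e.g. bee-colony trial counters) to the result's `debug` element.
#' @param ga Genetic algorithm: `pc` crossover prob (0.9), `pm` per-gene
#'   mutation prob (0.1), `sigma` mutation scale as a fraction of each
#'   coordinate range (0.1), `tournament` size (3); elitism of 1 is built in.
#' @param pso Particle swarm: inertia `w` (0.7), cognitive `c1` (1.5),
#'   social `c2` (1.5), `vclamp` velocity clamp as a fraction of range (0.5).
#' @param aco Ant colony: `alpha` pheromone exponent (1), `beta` heuristic
#'   exponent (1), `rho` evaporation in (0,1) (0.1), `Q` deposit scale (1),
#'   `tau0` initial pheromone (1), `tau_min` pheromone floor (1e-9), `eta`
#'   optional named list of per-coordinate heuristic desirability vectors
#'   (default uninformative).
#' @param sa Simulated annealing: `t0` initial temperature (1), `gamma`
#'   geometric cooling rate in (0,1) (0.95), `step` Gaussian proposal scale
#'   as a fraction of range (0.15), `chains` independent chains (defaults to
#'   `population`).
#' @param de Differential evolution (rand/1/bin): scale factor `f` (0.5),
#'   crossover probability `cr` (0.9).
#' @param abc Artificial bee colony: `limit` trials before a source is
#'   abandoned to a scout (20).
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(population = 30, iterations = 200, seed = 1,
                             cache = FALSE, debug = FALSE,
                             ga = list(), pso = list(), aco = list(),
                             sa = list(), de = list(), abc = list()) {
  if (!is_count(population, min = 2)) {
    stop_config("optimizer_config: `population` must be an integer >= 2")
  }
  if (!is_count(iterations)) {
    stop_config("optimizer_config: `iterations` must be an integer >= 1")
  }
  if (!is_count(seed, min = 0)) {
    stop_config("optimizer_config: `seed` must be a non-negative integer")
  }
  defaults <- list(
    ga = list(pc = 0.9, pm = 0.1, sigma = 0.1, tournament = 3),
    pso = list(w = 0.7, c1 = 1.5, c2 = 1.5, vclamp = 0.5),
    aco = list(alpha = 1, beta = 1, rho = 0.1, Q = 1, tau0 = 1,
               tau_min = 1e-9, eta = NULL),
    sa = list(t0 = 1, gamma = 0.95, step = 0.15, chains = NULL),
    de = list(f = 0.5, cr = 0.9),
    abc = list(limit = 20)
  )
  merge_alg <- function(nm, user) {
    unknown <- setdiff(names(user), names(defaults[[nm]]))
    if (length(unknown)) {
      stop_config("optimizer_config: unknown `", nm, "` option(s): ",
                  paste(unknown, collapse = ", "))
    }
    utils::modifyList(defaults[[nm]], user)
  }
  cfg <- list(
    population = as.integer(population), iterations = as.integer(iterations),
    seed = as.integer(seed), cache = isTRUE(cache), debug = isTRUE(debug),
    ga = merge_alg("ga", ga), pso = merge_alg("pso", pso),
    aco = merge_alg("aco", aco), sa = merge_alg("sa", sa),
    de = merge_alg("de", de), abc = merge_alg("abc", abc)
  )
  for (p in c("pc", "pm")) {
    if (!is_number(cfg$ga[[p]]) || cfg$ga[[p]] < 0 || cfg$ga[[p]] > 1) {
      stop_config("optimizer_config: ga$", p, " must be in [0, 1]")
    }
  }
  if (!is_number(cfg$aco$rho) || cfg$aco$rho <= 0 || cfg$aco$rho > 1) {
    stop_config("optimizer_config: aco$rho must be in (0, 1]")
  }
  if (!is_number(cfg$sa$gamma) || cfg$sa$gamma <= 0 || cfg$sa$gamma >= 1) {
    stop_config("optimizer_config: sa$gamma must be in (0, 1)")
  }
  if (!is_number(cfg$sa$t0) || cfg$sa$t0 <= 0) {
    stop_config("optimizer_config: sa$t0 must be > 0")
  }
  if (!is_number(cfg$de$cr) || cfg$de$cr < 0 || cfg$de$cr > 1) {
    stop_config("optimizer_config: de$cr must be in [0, 1]")
  }
  if (!is_count(cfg$abc$limit)) {
    stop_config("optimizer_config: abc$limit must be an integer >= 1")
  }
  if (!is.null(cfg$sa$chains) && !is_count(cfg$sa$chains)) {
    stop_config("optimizer_config: sa$chains must be an integer >= 1")
  }
  structure(cfg, class = "optimizer_config")
}

as_optimizer_config <- function(config) {
  if (inherits(config, "optimizer_config")) return(config)
  if (is.list(config)) return(do.call(optimizer_config, config))
  stop_config("`config` must be an optimizer_config or a list of options")
}

check_space <- function(space, fn) {
  if (!inherits(space, "decision_space")) {
    stop_config(fn, ": `space` must be a decision_space (t_min <= t_max etc.)")
  }
}

init_population <- function(space, m) {
  lo <- space_lower(space)
  hi <- space_upper(space)
  matrix(stats::runif(m * 10, rep(lo, each = m), rep(hi, each = m)),
         nrow = m)
}

clip_matrix <- function(X, lo, hi) {
  for (j in seq_len(ncol(X))) X[, j] <- clamp(X[, j], lo[j], hi[j])
  X
}

new_run_result <- function(algorithm, space, objective, ev, best_x,
                           best_fitness, trajectory, seed, debug = NULL) {
  D <- decode_candidates(space, best_x)
  ofn <- attr(objective, "outcome_fn")
  res <- structure(
    list(
      algorithm = algorithm,
      best_schedule = row_to_schedule(D[1, ]),
      best_fitness = best_fitness,
      trajectory = trajectory,
      evaluations = attr(ev, "env")$evals,
      outcome_summary = if (!is.null(ofn)) ofn(D[1, ]) else NULL,
      seed = seed
    ),
    class = "run_result"
  )
  if (!is.null(debug)) res$debug <- debug
  res
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result: %s> best fitness %.6f after %d evaluations\n",
              x$algorithm, x$best_fitness, x$evaluations))
  print(x$best_schedule)
  if (!is.null(x$outcome_summary)) {
    o <- x$outcome_summary
    cat(sprintf(
      "  cohort means: dBMI %.3f, dF %.2f, %.1f kcal/session, dHR %.2f bpm\n",
      o$delta_bmi, o$delta_f, o$calories, o$delta_hr))
  }
  invisible(x)
}

tournament_select <- function(fit, m, k) {
  S <- matrix(sample.int(m, m * k, replace = TRUE), m, k)
  S[cbind(seq_len(m), max.col(matrix(fit[S], m, k), ties.method = "first"))]
}

#' Run the genetic algorithm
#'
#' Real-valued encoding with repair (see [decode_candidates()]), tournament
#' selection, per-gene blend crossover, Gaussian mutation, and elitism of
#' one: each generation's worst offspring is replaced by the previous
#' generation's best individual.
#'
#' @param objective Vectorized objective over decoded candidate matrices
#'   (higher is better), e.g. from [schedule_objective()].
#' @param space A [decision_space()].
#' @param config An [optimizer_config()].
#' @return A `run_result` with the best schedule, best fitness, the
#'   non-decreasing best-so-far trajectory (one entry per iteration), the
#'   exact evaluation count, the cohort-mean outcomes at the optimum (when
#'   the objective provides them), and the seed.
#' @export
run_ga <- function(objective, space, config = optimizer_config()) {
  config <- as_optimizer_config(config)
  check_space(space, "run_ga")
  set.seed(config$seed)
  m <- config$population
  lo <- space_lower(space)
  hi <- space_upper(space)
  h <- config$ga
  ev <- make_evaluator(objective, space, cache = config$cache)

  P <- init_population(space, m)
  fit <- ev(P)
  best_i <- which.max(fit)
  best_x <- P[best_i, ]
  best_f <- fit[best_i]
  traj <- numeric(config$iterations)

  for (it in seq_len(config$iterations)) {
    p1 <- tournament_select(fit, m, h$tournament)
    p2 <- tournament_select(fit, m, h$tournament)
    C <- P[p1, , drop = FALSE]
    do_cx <- stats::runif(m) < h$pc
    if (any(do_cx)) {
      U <- matrix(stats::runif(m * 10), m)
      blend <- U * P[p1, , drop = FALSE] + (1 - U) * P[p2, , drop = FALSE]
      C[do_cx, ] <- blend[do_cx, ]
    }
    mut <- matrix(stats::runif(m * 10) < h$pm, m)
    noise <- matrix(stats::rnorm(m * 10), m) * rep(h$sigma * (hi - lo), each = m)
    C <- clip_matrix(C + mut * noise, lo, hi)

    cfit <- ev(C)
    # elitism: carry the parents' best over the worst child
    pb <- which.max(fit)
    wi <- which.min(cfit)
    if (fit[pb] > cfit[wi]) {
      C[wi, ] <- P[pb, ]
      cfit[wi] <- fit[pb]
    }
    P <- C
    fit <- cfit
    gi <- which.max(fit)
    if (fit[gi] > best_f) {
      best_f <- fit[gi]
      best_x <- P[gi, ]
    }
    traj[it] <- best_f
  }
  new_run_result("ga", space, objective, ev, best_x, best_f, traj, config$seed)
}

#' Run particle swarm optimization
#'
#' Standard inertia-weight velocity/position updates with cognitive and
#' social attraction, per-coordinate velocity clamping, position clipping to
#' bounds and simplex repair at decode time. Velocities start at zero, so
#' with `w = c1 = c2 = 0` particles never move.
#'
#' @inheritParams run_ga
#' @return A `run_result`; see [run_ga()].
#' @export
run_pso <- function(objective, space, config = optimizer_config()) {
  config <- as_optimizer_config(config)
  check_space(space, "run_pso")
  set.seed(config$seed)
  m <- config$population
  lo <- space_lower(space)
  hi <- space_upper(space)
  h <- config$pso
  vmax <- h$vclamp * (hi - lo)
  ev <- make_evaluator(objective, space, cache = config$cache)

  X <- init_population(space, m)
  V <- matrix(0, m, 10)
  fit <- ev(X)
  pbest <- X
  pfit <- fit
  gi <- which.max(fit)
  gbest <- X[gi, ]
  gfit <- fit[gi]
  traj <- numeric(config$iterations)

  for (it in seq_len(config$iterations)) {
    R1 <- matrix(stats::runif(m * 10), m)
    R2 <- matrix(stats::runif(m * 10), m)
    V <- h$w * V + h$c1 * R1 * (pbest - X) +
      h$c2 * R2 * (matrix(gbest, m, 10, byrow = TRUE) - X)
    V <- clip_matrix(V, -vmax, vmax)
    X <- clip_matrix(X + V, lo, hi)
    fit <- ev(X)
    better <- fit > pfit
    pbest[better, ] <- X[better, , drop = FALSE]
    pfit[better] <- fit[better]
    gi <- which.max(pfit)
    if (pfit[gi] > gfit) {
      gfit <- pfit[gi]
      gbest <- pbest[gi, ]
    }
    traj[it] <- gfit
  }
  new_run_result("pso", space, objective, ev, gbest, gfit, traj, config$seed)
}

#' Run ant colony optimization
#'
#' Requires a fully discretized space: each ant selects one level per
#' coordinate with probability proportional to `tau^alpha * eta^beta`
#' (pheromone intensity times heuristic desirability; `eta` defaults to
#' uninformative). After each iteration pheromone evaporates as
#' `tau <- (1 - rho) * tau`, the iteration-best ant deposits
#' `Q * max(fitness, 0)` on its chosen levels, and pheromone is floored at
#' `tau_min`.
#'
#' @inheritParams run_ga
#' @return A `run_result`; see [run_ga()]. With `debug = TRUE` the result
#'   carries the final pheromone state.
#' @export
run_aco <- function(objective, space, config = optimizer_config()) {
  config <- as_optimizer_config(config)
  check_space(space, "run_aco")
  if (!is_discrete(space)) {
    stop_config("run_aco: space must be discretized (see discretize_space)")
  }
  set.seed(config$seed)
  m <- config$population
  h <- config$aco
  levels <- space$levels
  nlev <- vapply(levels, length, integer(1))
  tau <- lapply(nlev, function(L) rep(h$tau0, L))
  eta <- h$eta %||% lapply(nlev, function(L) rep(1, L))
  ev <- make_evaluator(objective, space, cache = config$cache)

  best_x <- NULL
  best_f <- -Inf
  traj <- numeric(config$iterations)

  for (it in seq_len(config$iterations)) {
    Lidx <- matrix(0L, m, 10)
    X <- matrix(0, m, 10)
    for (j in 1:10) {
      p <- tau[[j]]^h$alpha * eta[[j]]^h$beta
      Lidx[, j] <- if (nlev[j] == 1) rep(1L, m) else {
        sample.int(nlev[j], m, replace = TRUE, prob = p)
      }
      X[, j] <- levels[[j]][Lidx[, j]]
    }
    fit <- ev(X)
    b <- which.max(fit)
    dep <- h$Q * max(fit[b], 0)
    for (j in 1:10) {
      tau[[j]] <- pmax((1 - h$rho) * tau[[j]], h$tau_min)
      tau[[j]][Lidx[b, j]] <- tau[[j]][Lidx[b, j]] + dep
    }
    if (fit[b] > best_f) {
      best_f <- fit[b]
      best_x <- X[b, ]
    }
    traj[it] <- best_f
  }
  new_run_result("aco", space, objective, ev, best_x, best_f, traj,
                 config$seed,
                 debug = if (config$debug) list(tau = tau) else NULL)
}

#' Metropolis acceptance probability of simulated annealing
#'
#' Returns `exp(-delta_e / temperature)` for a worsening move
#' (`delta_e > 0`) and 1 otherwise: improvements are always accepted.
#'
#' @param delta_e Fitness change of the proposal, positive when worse.
#'   Vectorized.
#' @param temperature Current temperature, > 0.
#' @return Acceptance probability in `[0, 1]`.
#' @export
#' @examples
#' sa_accept(1, 1) # exp(-1)
sa_accept <- function(delta_e, temperature) {
  if (!is_number(temperature) || temperature <= 0) {
    stop_config("sa_accept: `temperature` must be > 0")
  }
  ifelse(delta_e <= 0, 1, exp(-delta_e / temperature))
}

#' Temperature of the geometric cooling schedule
#'
#' `T(t) = t0 * gamma^t`: the temperature after `steps` applications of the
#' cooling rule `T(t+1) = gamma * T(t)`.
#'
#' @param t0 Initial temperature, > 0.
#' @param gamma Cooling rate in (0, 1).
#' @param steps Number of cooling steps, >= 0.
#' @return The temperature after `steps` steps.
#' @export
#' @examples
#' sa_temperature(100, 0.95, 10) # ~59.874
sa_temperature <- function(t0, gamma, steps) {
  if (!is_number(t0) || t0 <= 0) stop_config("sa_temperature: `t0` must be > 0")
  if (!is_number(gamma) || gamma <= 0 || gamma >= 1) {
    stop_config("sa_temperature: `gamma` must be in (0, 1)")
  }
  if (!is_count(steps, min = 0)) {
    stop_config("sa_temperature: `steps` must be a non-negative integer")
  }
  t0 * gamma^steps
}

#' Run simulated annealing
#'
#' Runs `chains` independent chains (default: `population`, honouring the
#' shared evaluation budget with the population methods). Each chain makes a
#' Gaussian proposal per iteration, accepts by the Metropolis rule
#' [sa_accept()], and the temperature follows the geometric schedule
#' `T(t+1) = gamma * T(t)` from `t0`. The result is the best candidate
#' evaluated across all chains.
#'
#' @inheritParams run_ga
#' @return A `run_result`; see [run_ga()].
#' @export
run_sa <- function(objective, space, config = optimizer_config()) {
  config <- as_optimizer_config(config)
  check_space(space, "run_sa")
  set.seed(config$seed)
  m <- config$sa$chains %||% config$population
  lo <- space_lower(space)
  hi <- space_upper(space)
  h <- config$sa
  ev <- make_evaluator(objective, space, cache = config$cache)

  X <- init_population(space, m)
  fit <- ev(X)
  bi <- which.max(fit)
  best_x <- X[bi, ]
  best_f <- fit[bi]
  temp <- h$t0
  traj <- numeric(config$iterations)

  for (it in seq_len(config$iterations)) {
    prop <- clip_matrix(
      X + matrix(stats::rnorm(m * 10), m) * rep(h$step * (hi - lo), each = m),
      lo, hi
    )
    fp <- ev(prop)
    acc <- stats::runif(m) < sa_accept(fit - fp, temp)
    X[acc, ] <- prop[acc, , drop = FALSE]
    fit[acc] <- fp[acc]
    pb <- which.max(fp)
    if (fp[pb] > best_f) {
      best_f <- fp[pb]
      best_x <- prop[pb, ]
    }
    temp <- h$gamma * temp
    traj[it] <- best_f
  }
  new_run_result("sa", space, objective, ev, best_x, best_f, traj, config$seed)
}

#' Differential-evolution donor vector
#'
#' `v = x_r1 + F * (x_r2 - x_r3)`. When a `space` is supplied the donor is
#' clipped to its coordinate bounds (full repair happens at decode time
#' inside [run_de()]); otherwise the raw donor is returned.
#'
#' @param x_r1,x_r2,x_r3 Decision vectors of equal length.
#' @param f Scale factor.
#' @param space Optional [decision_space()] for bound clipping.
#' @return The donor vector.
#' @export
#' @examples
#' de_mutate(c(1, 2), c(3, 4), c(1, 1), f = 0.5) # c(2, 3.5)
de_mutate <- function(x_r1, x_r2, x_r3, f, space = NULL) {
  if (length(x_r1) != length(x_r2) || length(x_r1) != length(x_r3)) {
    stop_config("de_mutate: vectors must have equal length")
  }
  v <- x_r1 + f * (x_r2 - x_r3)
  if (!is.null(space)) v <- clamp(v, space_lower(space), space_upper(space))
  v
}

#' Differential-evolution binomial crossover
#'
#' Component `j` of the trial vector takes the donor value when a uniform
#' draw falls below `cr` or `j` is the guaranteed donor index (drawn
#' uniformly, so the trial always differs from the target when the donor
#' does); otherwise it keeps the target value.
#'
#' @param target,donor Decision vectors of equal length.
#' @param cr Crossover probability in `[0, 1]`.
#' @param seed Optional seed for a reproducible standalone call.
#' @return The trial vector.
#' @export
de_crossover <- function(target, donor, cr, seed = NULL) {
  if (!is_number(cr) || cr < 0 || cr > 1) {
    stop_config("de_crossover: `cr` must be in [0, 1]")
  }
  if (length(target) != length(donor)) {
    stop_config("de_crossover: vectors must have equal length")
  }
  if (!is.null(seed)) set.seed(seed)
  d <- length(target)
  jrand <- sample.int(d, 1)
  take <- stats::runif(d) < cr
  take[jrand] <- TRUE
  ifelse(take, donor, target)
}

#' Run differential evolution (DE/rand/1/bin)
#'
#' For each target vector, a donor is built from three distinct random
#' population members via [de_mutate()], crossed over with the target via
#' binomial crossover, and the trial replaces the target when its fitness is
#' at least as good (greedy selection).
#'
#' @inheritParams run_ga
#' @return A `run_result`; see [run_ga()].
#' @export
run_de <- function(objective, space, config = optimizer_config()) {
  config <- as_optimizer_config(config)
  check_space(space, "run_de")
  m <- config$population
  if (m < 4) {
    stop_config("run_de: population must be >= 4 so mutation indices can be ",
                "distinct from the target")
  }
  set.seed(config$seed)
  lo <- space_lower(space)
  hi <- space_upper(space)
  h <- config$de
  ev <- make_evaluator(objective, space, cache = config$cache)

  X <- init_population(space, m)
  fit <- ev(X)
  bi <- which.max(fit)
  best_x <- X[bi, ]
  best_f <- fit[bi]
  traj <- numeric(config$iterations)

  for (it in seq_len(config$iterations)) {
    U <- X
    for (i in seq_len(m)) {
      r <- sample((seq_len(m))[-i], 3)
      v <- de_mutate(X[r[1], ], X[r[2], ], X[r[3], ], h$f)
      U[i, ] <- de_crossover(X[i, ], v, h$cr)
    }
    U <- clip_matrix(U, lo, hi)
    fu <- ev(U)
    take <- fu >= fit
    X[take, ] <- U[take, , drop = FALSE]
    fit[take] <- fu[take]
    bi <- which.max(fit)
    if (fit[bi] > best_f) {
      best_f <- fit[bi]
      best_x <- X[bi, ]
    }
    traj[it] <- best_f
  }
  new_run_result("de", space, objective, ev, best_x, best_f, traj, config$seed)
}

# fitness-proportional onlooker selection probabilities (shifted so the
# worst source keeps a vanishing but positive probability)
abc_selection_probs <- function(fit) {
  p <- fit - min(fit) + 1e-12
  p / sum(p)
}

#' Run artificial bee colony optimization
#'
#' `population / 2` food sources. Employed phase: each source is perturbed in
#' one random coordinate towards/away from a random partner and replaced
#' greedily; sources whose trial counter exceeded `limit` are re-initialized
#' by scouts at the start of the phase (the scout's fresh source is evaluated
#' in place of a perturbation, preserving the evaluation budget). Onlooker
#' phase: sources are selected with probability proportional to shifted
#' fitness and perturbed the same way. Trial counters reset on improvement
#' and increment otherwise.
#'
#' @inheritParams run_ga
#' @return A `run_result`; see [run_ga()]. With `debug = TRUE` the result
#'   carries the per-iteration trial counters and scout events.
#' @export
run_abc <- function(objective, space, config = optimizer_config()) {
  config <- as_optimizer_config(config)
  check_space(space, "run_abc")
  set.seed(config$seed)
  n_src <- max(2L, config$population %/% 2L)
  lo <- space_lower(space)
  hi <- space_upper(space)
  limit <- config$abc$limit
  ev <- make_evaluator(objective, space, cache = config$cache)

  X <- init_population(space, n_src)
  fit <- ev(X)
  trials <- integer(n_src)
  bi <- which.max(fit)
  best_x <- X[bi, ]
  best_f <- fit[bi]
  traj <- numeric(config$iterations)
  dbg <- if (config$debug) list(trials = list(), scouts = list()) else NULL

  perturb <- function(base_row, partner_row) {
    d <- sample.int(10, 1)
    out <- base_row
    out[d] <- base_row[d] +
      stats::runif(1, -1, 1) * (base_row[d] - partner_row[d])
    clamp(out, lo, hi)
  }

  for (it in seq_len(config$iterations)) {
    # employed phase with folded scouts
    scouts <- which(trials > limit)
    Xe <- X
    for (i in seq_len(n_src)) {
      if (i %in% scouts) {
        Xe[i, ] <- init_population(space, 1)
      } else {
        k <- sample((seq_len(n_src))[-i], 1)
        Xe[i, ] <- perturb(X[i, ], X[k, ])
      }
    }
    fe <- ev(Xe)
    replace <- fe > fit | seq_len(n_src) %in% scouts
    X[replace, ] <- Xe[replace, , drop = FALSE]
    fit[replace] <- fe[replace]
    trials <- ifelse(replace, 0L, trials + 1L)

    # onlooker phase
    sel <- sample.int(n_src, n_src, replace = TRUE,
                      prob = abc_selection_probs(fit))
    Xo <- matrix(0, n_src, 10)
    for (j in seq_len(n_src)) {
      k <- sample((seq_len(n_src))[-sel[j]], 1)
      Xo[j, ] <- perturb(X[sel[j], ], X[k, ])
    }
    fo <- ev(Xo)
    for (j in seq_len(n_src)) {
      s <- sel[j]
      if (fo[j] > fit[s]) {
        X[s, ] <- Xo[j, ]
        fit[s] <- fo[j]
        trials[s] <- 0L
      } else {
        trials[s] <- trials[s] + 1L
      }
    }

    bi <- which.max(fit)
    if (fit[bi] > best_f) {
      best_f <- fit[bi]
      best_x <- X[bi, ]
    }
    traj[it] <- best_f
    if (config$debug) {
      dbg$trials[[it]] <- trials
      dbg$scouts[[it]] <- scouts
    }
  }
  new_run_result("abc", space, objective, ev, best_x, best_f, traj,
                 config$seed, debug = dbg)
}

#' Dispatch an optimizer by name
#'
#' @param algorithm One of `"ga"`, `"pso"`, `"aco"`, `"sa"`, `"de"`, `"abc"`.
#' @inheritParams run_ga
#' @return A `run_result`.
#' @export
run_optimizer <- function(algorithm, objective, space,
                          config = optimizer_config()) {
  fn <- switch(algorithm,
    ga = run_ga, pso = run_pso, aco = run_aco,
    sa = run_sa, de = run_de, abc = run_abc,
    stop_config("run_optimizer: unknown algorithm '", algorithm, "'")
  )
  fn(objective, space, config)
}
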