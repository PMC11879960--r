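# Decision space and candidate encoding.
#
# All six optimizers share one real-vector encoding of a weekly schedule:
#   (t_session, n_sessions, a_aerobic..a_recreational, i_low..i_vigorous)
# i.e. 10 coordinates. Constraints are handled by repair, not penalties:
# coordinates are clipped to bounds, n_sessions is rounded to an integer,
# both proportion blocks are renormalized onto their simplexes, and the
# session duration is shrunk when the weekly-hours cap would be exceeded.
# A space may additionally carry per-coordinate discretization levels; the
# ant-colony optimizer and the exhaustive oracle require them, and the
# continuous algorithms snap candidates to the nearest level so all six
# methods explore the identical finite grid when one is supplied.

#' @rdname decision_space
#' @format NULL
#' @export
SCHEDULE_COORDS <- c(
  "t_session", "n_sessions",
  "a_aerobic", "a_strength", "a_team", "a_flexibility", "a_recreational",
  "i_low", "i_moderate", "i_vigorous"
)

#' Define the schedule decision space
#'
#' `SCHEDULE_COORDS` names the 10 coordinates of the shared encoding.
#'
#' @param t_bounds Session-duration bounds in hours, `0 <= t_min <= t_max`.
#' @param n_bounds Integer sessions-per-week bounds within `[1, 7]`.
#' @param t_max_weekly Cap on weekly PE hours (`n_sessions * t_session`);
#'   must be at least `t_bounds[2]`.
#' @param levels Optional named list of per-coordinate discretization levels
#'   (see [discretize_space()]).
#' @return An object of class `decision_space`.
#' @export
#' @examples
#' sp <- decision_space()
#' sp_d <- discretize_space(sp)
decision_space <- function(t_bounds = c(0.5, 2), n_bounds = c(1L, 7L),
                           t_max_weekly = 10, levels = NULL) {
  if (length(t_bounds) != 2 || !all(is.finite(t_bounds)) ||
      t_bounds[1] < 0 || t_bounds[1] > t_bounds[2]) {
    stop_config("decision_space: `t_bounds` must satisfy 0 <= t_min <= t_max")
  }
  if (length(n_bounds) != 2 || !all(n_bounds == floor(n_bounds)) ||
      n_bounds[1] < 1 || n_bounds[2] > 7 || n_bounds[1] > n_bounds[2]) {
    stop_config("decision_space: `n_bounds` must be integer bounds within [1, 7]")
  }
  if (!is_number(t_max_weekly) || t_max_weekly < t_bounds[2]) {
    stop_config("decision_space: `t_max_weekly` must be >= t_bounds[2]")
  }
  space <- structure(
    list(t_bounds = as.numeric(t_bounds),
         n_bounds = as.integer(n_bounds),
         t_max_weekly = t_max_weekly,
         levels = NULL),
    class = "decision_space"
  )
  if (!is.null(levels)) space <- discretize_space(space, levels)
  space
}

#' Discretize a decision space
#'
#' Attaches per-coordinate level sets. With the defaults, session duration
#' gets `t_levels` equispaced values across its bounds, session count gets
#' every integer in its range, and every proportion coordinate gets
#' `mix_levels` equispaced values on the unit interval (proportion levels are
#' renormalized onto the simplex at decode time).
#'
#' @param space A [decision_space()].
#' @param levels Either a named list giving a sorted numeric level vector for
#'   each of the 10 coordinates, or `NULL` to build defaults.
#' @param t_levels,mix_levels Defaults used when `levels` is `NULL`.
#' @return The space with a complete `levels` list.
#' @export
discretize_space <- function(space, levels = NULL, t_levels = 7, mix_levels = 3) {
  stopifnot(inherits(space, "decision_space"))
  if (is.null(levels)) {
    levels <- c(
      list(
        t_session = seq(space$t_bounds[1], space$t_bounds[2],
                        length.out = t_levels),
        n_sessions = as.numeric(seq(space$n_bounds[1], space$n_bounds[2]))
      ),
      stats::setNames(
        rep(list(seq(0, 1, length.out = mix_levels)), 8),
        SCHEDULE_COORDS[3:10]
      )
    )
  }
  missing <- setdiff(SCHEDULE_COORDS, names(levels))
  if (length(missing)) {
    stop_config("discretize_space: no levels for coordinate(s): ",
                paste(missing, collapse = ", "))
  }
  for (nm in SCHEDULE_COORDS) {
    lv <- levels[[nm]]
    if (!is.numeric(lv) || length(lv) < 1 || is.unsorted(lv, strictly = TRUE)) {
      stop_config("discretize_space: levels for `", nm,
                  "` must be a strictly increasing numeric vector")
    }
  }
  space$levels <- levels[SCHEDULE_COORDS]
  space
}

is_discrete <- function(space) !is.null(space$levels)

space_lower <- function(space) {
  c(space$t_bounds[1], space$n_bounds[1], rep(0, 8))
}

space_upper <- function(space) {
  c(space$t_bounds[2], space$n_bounds[2], rep(1, 8))
}

#' Number of grid points of a discretized space
#' @param space A discretized [decision_space()].
#' @return Product of the per-coordinate level counts.
#' @export
space_grid_size <- function(space) {
  if (!is_discrete(space)) {
    stop_config("space_grid_size: space is not discretized")
  }
  prod(vapply(space$levels, length, numeric(1)))
}

snap_to_levels <- function(x, lv) {
  if (length(lv) == 1) return(rep(lv, length(x)))
  mids <- lv[-length(lv)] + diff(lv) / 2
  lv[findInterval(x, mids) + 1]
}

#' Decode raw candidate vectors into feasible schedules
#'
#' Applies the repair pipeline to a matrix of raw encoding vectors: clip to
#' bounds, snap to discretization levels when present, round the session
#' count, renormalize both proportion blocks onto their simplexes (an
#' all-zero block becomes uniform), and shrink `t_session` to
#' `t_max_weekly / n_sessions` when the weekly cap is exceeded.
#'
#' @param space A [decision_space()].
#' @param X Numeric matrix, one row per candidate, 10 columns in
#'   `SCHEDULE_COORDS` order (a bare vector is taken as one row).
#' @return A decoded feasible matrix with `SCHEDULE_COORDS` column names.
#' @export
decode_candidates <- function(space, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != 10) {
    stop_config("decode_candidates: candidates must have 10 coordinates")
  }
  lo <- space_lower(space)
  hi <- space_upper(space)
  for (j in 1:10) X[, j] <- clamp(X[, j], lo[j], hi[j])
  if (is_discrete(space)) {
    for (j in 1:10) X[, j] <- snap_to_levels(X[, j], space$levels[[j]])
  }
  X[, 2] <- round(X[, 2])

  renorm <- function(M, k) {
    s <- rowSums(M)
    bad <- s <= 1e-12
    M[bad, ] <- 1 / k
    s[bad] <- 1
    M / s
  }
  X[, 3:7] <- renorm(X[, 3:7, drop = FALSE], 5)
  X[, 8:10] <- renorm(X[, 8:10, drop = FALSE], 3)

  weekly <- X[, 1] * X[, 2]
  over <- weekly > space$t_max_weekly
  if (any(over)) {
    X[over, 1] <- space$t_max_weekly / X[over, 2]
  }
  colnames(X) <- SCHEDULE_COORDS
  X
}

# decoded row -> pe_schedule object
row_to_schedule <- function(d_row) {
  schedule(
    n_sessions = as.integer(round(d_row[["n_sessions"]])),
    t_session = d_row[["t_session"]],
    activity_mix = d_row[paste0("a_", ACTIVITIES)],
    intensity_mix = d_row[paste0("i_", INTENSITIES)]
  )
}

# assert that decoded candidates satisfy every decision-space constraint
assert_feasible <- function(space, D) {
  t <- D[, 1]
  n <- D[, 2]
  ok <- all(t >= space$t_bounds[1] - 1e-9) &&
    all(t <= space$t_bounds[2] + 1e-9) &&
    all(n == round(n)) &&
    all(n >= space$n_bounds[1]) && all(n <= space$n_bounds[2]) &&
    all(D[, 3:10] >= -1e-12) &&
    all(abs(rowSums(D[, 3:7, drop = FALSE]) - 1) <= 1e-9) &&
    all(abs(rowSums(D[, 8:10, drop = FALSE]) - 1) <= 1e-9) &&
    all(n * t <= space$t_max_weekly + 1e-9)
  if (!ok) stop("internal error: infeasible candidate reached the objective")
  invisible(TRUE)
}

# Evaluator shared by all optimizers: raw candidate matrix -> fitness vector.
# Decodes, asserts feasibility, counts objective evaluations, and (for fully
# discretized spaces, on request) caches values by grid index so repeated
# visits to a grid point do not recompute the objective. Cache hits still
# count as evaluations: `evals` reports how many candidate evaluations the
# algorithm requested.
make_evaluator <- function(objective, space, cache = FALSE) {
  env <- new.env(parent = emptyenv())
  env$evals <- 0L
  use_cache <- isTRUE(cache) && is_discrete(space)
  if (use_cache) {
    sizes <- vapply(space$levels, length, numeric(1))
    if (prod(sizes) > 5e6) use_cache <- FALSE
  }
  if (use_cache) {
    mult <- cumprod(c(1, sizes[-length(sizes)]))
    env$values <- rep(NA_real_, prod(sizes))
    level_index <- function(X) {
      idx <- 1
      for (j in 1:10) {
        lv <- space$levels[[j]]
        ji <- if (length(lv) == 1) rep(1L, nrow(X)) else {
          mids <- lv[-length(lv)] + diff(lv) / 2
          findInterval(X[, j], mids) + 1L
        }
        idx <- idx + (ji - 1L) * mult[j]
      }
      idx
    }
    eval_fn <- function(X) {
      if (is.null(dim(X))) X <- matrix(X, nrow = 1)
      env$evals <- env$evals + nrow(X)
      keys <- level_index(decode_raw(space, X))
      miss <- which(is.na(env$values[keys]))
      if (length(miss)) {
        u <- unique(keys[miss])
        D <- decode_candidates(space, X[match(u, keys), , drop = FALSE])
        assert_feasible(space, D)
        env$values[u] <- objective(D)
      }
      env$values[keys]
    }
  } else {
    eval_fn <- function(X) {
      if (is.null(dim(X))) X <- matrix(X, nrow = 1)
      env$evals <- env$evals + nrow(X)
      D <- decode_candidates(space, X)
      assert_feasible(space, D)
      objective(D)
    }
  }
  attr(eval_fn, "env") <- env
  eval_fn
}

# clip+snap only (raw grid coordinates, before simplex repair) -- used to
# identify the grid cell of a candidate for caching
decode_raw <- function(space, X) {
  lo <- space_lower(space)
  hi <- space_upper(space)
  for (j in 1:10) {
    X[, j] <- snap_to_levels(clamp(X[, j], lo[j], hi[j]), space$levels[[j]])
  }
  X
}

#' Exhaustive search over a discretized decision space
#'
#' Evaluates the objective at every grid point of a fully discretized space
#' and returns the exact argmax. Ties are broken deterministically in favour
#' of the lexicographically smallest level-index tuple (coordinates ordered
#' as `SCHEDULE_COORDS`). Used as the ground-truth oracle in optimizer tests.
#'
#' @param objective Vectorized objective over decoded candidate matrices.
#' @param space A discretized [decision_space()] with at most `max_points`
#'   grid points.
#' @param max_points Enumeration guard (default 1e6).
#' @return List with `best_x` (raw grid point), `best_schedule`
#'   (decoded [schedule()]), `best_fitness`, and `n_points`.
#' @export
exhaustive_oracle <- function(objective, space, max_points = 1e6) {
  if (!is_discrete(space)) {
    stop_config("exhaustive_oracle: space must be discretized")
  }
  n_pts <- space_grid_size(space)
  if (n_pts > max_points) {
    stop_config("exhaustive_oracle: grid has ", n_pts,
                " points, exceeding the limit of ", max_points)
  }
  # lexicographic row order in SCHEDULE_COORDS: build reversed so the last
  # coordinate varies fastest, then restore column order
  G <- as.matrix(do.call(expand.grid, rev(space$levels)))
  G <- G[, rev(seq_len(ncol(G))), drop = FALSE]
  colnames(G) <- SCHEDULE_COORDS
  D <- decode_candidates(space, G)
  fit <- objective(D)
  best <- which.max(fit) # first (lexicographically smallest) maximizer
  list(
    best_x = G[best, ],
    best_schedule = row_to_schedule(D[best, ]),
    best_fitness = fit[best],
    n_points = n_pts
  )
}
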