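# Shared fixtures, all built in code.

tiny_cohort <- function(n = 20, seed = 1) {
  generate_cohort(cohort_spec(n_students = n, seed = seed))
}

# Discretized toy decision space (400 grid points): session duration and
# count vary, the aerobic share trades off against a fixed strength share,
# and the vigorous share trades off against a fixed low-intensity share.
# The weekly cap is slack so no cap repair occurs on the grid.
toy_space <- function() {
  decision_space(
    t_bounds = c(0.5, 2), n_bounds = c(1L, 7L), t_max_weekly = 20,
    levels = list(
      t_session = seq(0.5, 2, length.out = 5),
      n_sessions = c(1, 3, 5, 7),
      a_aerobic = seq(0, 1, by = 0.25),
      a_strength = 0.5, a_team = 0, a_flexibility = 0, a_recreational = 0,
      i_low = 0.2, i_moderate = 0,
      i_vigorous = c(0, 0.25, 0.5, 1)
    )
  )
}

toy_objective <- function(n = 5, seed = 11) {
  schedule_objective(tiny_cohort(n, seed))
}

# 1-D concave benchmark: only t_session is free, maximum at t = 7.3
oneD_space <- function() {
  decision_space(t_bounds = c(0, 10), n_bounds = c(1L, 1L), t_max_weekly = 10)
}

oneD_objective <- function() {
  function(D) -(D[, "t_session"] - 7.3)^2
}

weekly_hours <- function(res) {
  res$best_schedule$n_sessions * res$best_schedule$t_session
}
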