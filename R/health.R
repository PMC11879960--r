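# Health model: basal metabolic rate, MET-based caloric expenditure, the
# dose-response layer mapping a candidate weekly schedule to predicted
# outcome deltas (BMI reduction, fitness-score gain, per-session calories,
# resting-heart-rate reduction), and the weighted scalarization that turns
# the four outcomes into a single fitness score.

ACTIVITIES <- c("aerobic", "strength", "team", "flexibility", "recreational")
INTENSITIES <- c("low", "moderate", "vigorous")

#' Default effective MET table
#'
#' Activity-by-intensity metabolic-equivalent values used by
#' [effective_met()]. The caloric-expenditure formula multiplies the raw
#' MET-hour product by `(1 + BMR/1000)`, a factor of roughly 2-2.5 for
#' school-age students, so the defaults here are *effective* MET values
#' calibrated so that a fully vigorous aerobic session at the weekly-time cap
#' produces per-session energy expenditures in the 300-400 kcal range typical
#' of reported school PE interventions. They keep the compendium ordering
#' (aerobic > team > strength > recreational > flexibility, and vigorous >
#' moderate > low) and can be overridden through [response_params()].
#'
#' @return A 5 x 3 numeric matrix, rows `ACTIVITIES`, columns `INTENSITIES`.
#' @export
default_met_table <- function() {
  matrix(
    c(
      1.30, 1.70, 2.20,  # aerobic
      1.10, 1.30, 1.50,  # strength
      1.15, 1.45, 1.80,  # team
      1.00, 1.10, 1.20,  # flexibility
      1.05, 1.25, 1.55   # recreational
    ),
    nrow = 5, byrow = TRUE,
    dimnames = list(ACTIVITIES, INTENSITIES)
  )
}

#' Dose-response parameters of the health model
#'
#' The outcome deltas used by the fitness function are defined in the source
#' data only as observed before/after differences; for schedule optimization
#' they must be predicted from a candidate schedule. This parameter set
#' defines a transparent, monotone, bounded closed-form response layer:
#' energy-balance BMI reduction (weekly kcal over a school-term horizon,
#' 7700 kcal per kg of body fat, capped), and saturating-exponential fitness
#' and heart-rate responses driven by weekly moderate-to-vigorous (MVPA) and
#' weekly aerobic hours respectively.
#'
#' @param horizon_weeks Weeks over which energy balance accumulates into a
#'   BMI change (default 12, one school term).
#' @param met_table Activity-by-intensity MET matrix (see
#'   [default_met_table()]); entries must lie in `[1, 15]`.
#' @param kcal_per_kg_fat Energy density of body fat (default 7700 kcal/kg).
#' @param bmi_cap Maximum predicted BMI reduction, kg/m^2.
#' @param f_gain_max Maximum fitness-score gain, points.
#' @param k_f Fitness saturation rate per weekly MVPA hour.
#' @param hr_drop_max Maximum resting-heart-rate reduction, bpm.
#' @param k_h Heart-rate saturation rate per weekly aerobic hour.
#' @return An object of class `response_params`.
#' @export
response_params <- function(horizon_weeks = 12, met_table = default_met_table(),
                            kcal_per_kg_fat = 7700, bmi_cap = 5,
                            f_gain_max = 20, k_f = 0.15,
                            hr_drop_max = 10, k_h = 0.2) {
  for (nm in c("horizon_weeks", "kcal_per_kg_fat", "bmi_cap", "f_gain_max",
               "k_f", "hr_drop_max", "k_h")) {
    v <- get(nm)
    if (!is_number(v) || v <= 0) {
      stop_config("response_params: `", nm, "` must be a positive number")
    }
  }
  if (!is.matrix(met_table) ||
      !identical(rownames(met_table), ACTIVITIES) ||
      !identical(colnames(met_table), INTENSITIES)) {
    stop_config("response_params: `met_table` must be a 5x3 matrix with ",
                "activity rows and intensity columns")
  }
  if (any(met_table < 1) || any(met_table > 15)) {
    stop_config("response_params: `met_table` entries must lie in [1, 15]")
  }
  structure(
    list(horizon_weeks = horizon_weeks, met_table = met_table,
         kcal_per_kg_fat = kcal_per_kg_fat, bmi_cap = bmi_cap,
         f_gain_max = f_gain_max, k_f = k_f,
         hr_drop_max = hr_drop_max, k_h = k_h),
    class = "response_params"
  )
}

#' Weights of the scalarized fitness function
#'
#' Four non-negative weights summing to one, applied to normalized BMI
#' reduction, fitness improvement, calories burned and heart-rate reduction.
#' Defaults 0.4/0.3/0.2/0.1 prioritize BMI reduction (childhood obesity),
#' then fitness, energy expenditure and cardiovascular response.
#'
#' @param w1,w2,w3,w4 Weights for BMI reduction, fitness improvement,
#'   calories burned and heart-rate reduction.
#' @return An object of class `fitness_weights`.
#' @export
fitness_weights <- function(w1 = 0.4, w2 = 0.3, w3 = 0.2, w4 = 0.1) {
  w <- c(w1 = w1, w2 = w2, w3 = w3, w4 = w4)
  if (!is.numeric(w) || length(w) != 4 || any(!is.finite(w)) || any(w < 0)) {
    stop_config("FitnessWeights: all weights must be finite and >= 0")
  }
  if (abs(sum(w) - 1) > 1e-9) {
    stop_config("FitnessWeights: weights must sum to 1 (got ", sum(w), ")")
  }
  structure(as.list(w), class = "fitness_weights")
}

#' Per-metric normalization bounds for the fitness function
#'
#' Raw outcome metrics live on very different scales (calories ~ 10^2 kcal,
#' heart-rate reduction ~ 10^0 bpm); combining them raw would let calories
#' swamp every other term. Each metric is therefore min-max scaled to the unit interval
#' by these decision-space bounds before weighting, which makes the weight
#' priorities meaningful. Scaled values are clipped to the unit interval.
#'
#' @param delta_bmi,delta_f,calories,delta_hr Length-2 `(lo, hi)` bounds.
#' @return An object of class `metric_norms`.
#' @export
metric_norms <- function(delta_bmi = c(0, 5), delta_f = c(0, 20),
                         calories = c(0, 800), delta_hr = c(0, 10)) {
  norms <- list(delta_bmi = delta_bmi, delta_f = delta_f,
                calories = calories, delta_hr = delta_hr)
  for (nm in names(norms)) {
    b <- norms[[nm]]
    if (length(b) != 2 || !all(is.finite(b)) || b[2] <= b[1]) {
      stop_config("metric_norms: `", nm, "` must be finite bounds with hi > lo")
    }
  }
  structure(norms, class = "metric_norms")
}

#' Construct a weekly PE schedule
#'
#' The decision vector of the optimization: weekly session count, session
#' duration, and two simplex-constrained mixes (time shares over five
#' activity types, and shares over three intensity levels).
#'
#' @param n_sessions Integer sessions per week, 1-7.
#' @param t_session Session duration in hours, > 0.
#' @param activity_mix Named or ordered numeric vector of 5 non-negative
#'   proportions (aerobic, strength, team, flexibility, recreational) summing
#'   to 1.
#' @param intensity_mix Numeric vector of 3 non-negative proportions
#'   (low, moderate, vigorous) summing to 1.
#' @return An object of class `pe_schedule`.
#' @export
#' @examples
#' schedule(5, 1.5, c(0.4, 0.2, 0.2, 0.1, 0.1), c(0.2, 0.5, 0.3))
schedule <- function(n_sessions, t_session, activity_mix, intensity_mix) {
  if (!is_count(n_sessions) || n_sessions < 1 || n_sessions > 7) {
    stop_config("schedule: `n_sessions` must be an integer in [1, 7]")
  }
  if (!is_number(t_session) || t_session < 0) {
    stop_config("schedule: `t_session` must be a non-negative number of hours")
  }
  check_simplex <- function(p, len, nm, names) {
    if (length(p) != len || any(!is.finite(p)) || any(p < 0) ||
        abs(sum(p) - 1) > 1e-9) {
      stop_config("schedule: `", nm, "` must be ", len,
                  " non-negative proportions summing to 1")
    }
    stats::setNames(as.numeric(p), names)
  }
  structure(
    list(
      n_sessions = as.integer(n_sessions),
      t_session = t_session,
      activity_mix = check_simplex(activity_mix, 5, "activity_mix", ACTIVITIES),
      intensity_mix = check_simplex(intensity_mix, 3, "intensity_mix", INTENSITIES)
    ),
    class = "pe_schedule"
  )
}

#' @export
print.pe_schedule <- function(x, ...) {
  cat(sprintf("<pe_schedule> %d sessions/week x %.2f h (%.2f h/week)\n",
              x$n_sessions, x$t_session, x$n_sessions * x$t_session))
  cat("  activity mix:  ",
      paste(sprintf("%s %.2f", names(x$activity_mix), x$activity_mix),
            collapse = ", "), "\n")
  cat("  intensity mix: ",
      paste(sprintf("%s %.2f", names(x$intensity_mix), x$intensity_mix),
            collapse = ", "), "\n")
  invisible(x)
}

#' Basal metabolic rate (Mifflin-style linear form)
#'
#' `BMR = 10 W + 6.25 H - 5 A + S` with the sex constant `S = +5` for males
#' and `-161` for females, in kcal/day.
#'
#' @param weight Body weight in kg, > 0. Vectorized.
#' @param height Height in cm, > 0.
#' @param age Age in years, > 0.
#' @param sex `"male"` or `"female"`.
#' @return Basal metabolic rate in kcal/day.
#' @export
#' @examples
#' bmr(70, 175, 30, "male") # 1648.75
bmr <- function(weight, height, age, sex) {
  if (any(!is.finite(weight) | weight <= 0) ||
      any(!is.finite(height) | height <= 0) ||
      any(!is.finite(age) | age <= 0)) {
    stop_config("bmr: weight, height and age must be positive")
  }
  if (!all(sex %in% c("male", "female"))) {
    stop_config("bmr: `sex` must be \"male\" or \"female\"")
  }
  s <- ifelse(sex == "male", 5, -161)
  10 * weight + 6.25 * height - 5 * age + s
}

#' Caloric expenditure of an activity bout
#'
#' `Calories = MET * W * t * (1 + BMR/1000)`: the raw MET-hour energy cost
#' scaled up by a basal-metabolic-rate factor that individualizes the
#' estimate.
#'
#' @param met Metabolic equivalent of task, >= 0. Vectorized.
#' @param weight Body weight in kg.
#' @param t Duration in hours, >= 0.
#' @param bmr_value Basal metabolic rate in kcal/day (see [bmr()]).
#' @return Energy expenditure in kcal.
#' @export
#' @examples
#' calories_burned(8, 50, 0.75, 1329) # 698.7
calories_burned <- function(met, weight, t, bmr_value) {
  if (any(!is.finite(met) | met < 0) || any(!is.finite(t) | t < 0) ||
      any(!is.finite(weight) | weight < 0) ||
      any(!is.finite(bmr_value) | bmr_value < 0)) {
    stop_config("calories_burned: inputs must be finite and non-negative")
  }
  met * weight * t * (1 + bmr_value / 1000)
}

#' Effective MET of a schedule
#'
#' The single MET value entering the caloric-expenditure formula, computed as
#' the activity-mix- and intensity-mix-weighted average of the MET table:
#' a convex combination, so always bounded by the table entries.
#'
#' @param sched A [schedule()].
#' @param params A [response_params()].
#' @return A single effective MET value.
#' @export
effective_met <- function(sched, params = response_params()) {
  if (!inherits(sched, "pe_schedule")) {
    stop_config("effective_met: `sched` must be a pe_schedule")
  }
  drop(sched$activity_mix %*% params$met_table %*% sched$intensity_mix)
}

#' Weekly and daily PE time of a schedule
#'
#' Weekly hours are `n_sessions * t_session`; daily hours divide by the
#' number of days in the school week. Both readings are returned; weekly
#' hours are used for reporting throughout the package.
#'
#' @param n_sessions Sessions per week, >= 0.
#' @param t_session Session duration in hours.
#' @param days_per_week Days in the schedule week, in `[5, 7]`.
#' @return List with `weekly_hours` and `daily_hours`.
#' @export
#' @examples
#' optimal_pe_time(5, 1.5, 5) # weekly 7.5, daily 1.5
optimal_pe_time <- function(n_sessions, t_session, days_per_week = 7) {
  if (!is_number(n_sessions) || n_sessions < 0) {
    stop_config("optimal_pe_time: `n_sessions` must be >= 0")
  }
  if (!is_number(days_per_week) || days_per_week < 5 || days_per_week > 7) {
    stop_config("optimal_pe_time: `days_per_week` must be in [5, 7]")
  }
  weekly <- n_sessions * t_session
  list(weekly_hours = weekly, daily_hours = weekly / days_per_week)
}

# Shared vectorized core of the response model.
#
# cohort: data frame with weight_kg, height_cm, age, sex, ...
# D: decoded candidate matrix (K rows, columns COORDS)
# Returns outcome components; delta_bmi and calories are S x K matrices
# (students x schedules), delta_f and delta_hr are length-K vectors
# (schedule-level responses shared across students).
outcome_components <- function(cohort, D, params) {
  w <- cohort$weight_kg
  h_m2 <- (cohort$height_cm / 100)^2
  b <- bmr(cohort$weight_kg, cohort$height_cm, cohort$age, cohort$sex)
  fac <- 1 + b / 1000

  A <- D[, paste0("a_", ACTIVITIES), drop = FALSE]
  I <- D[, paste0("i_", INTENSITIES), drop = FALSE]
  met <- unname(rowSums((A %*% params$met_table) * I))

  t_k <- unname(D[, "t_session"])
  n_k <- unname(D[, "n_sessions"])
  weekly <- n_k * t_k
  mvpa <- weekly * unname(I[, "i_moderate"] + I[, "i_vigorous"])
  aerobic <- weekly * unname(A[, "a_aerobic"])

  calories <- outer(w * fac, met * t_k)              # S x K, kcal/session
  weekly_kcal <- sweep(calories, 2, n_k, `*`)
  delta_bmi <- pmin(
    sweep(weekly_kcal * params$horizon_weeks / params$kcal_per_kg_fat,
          1, h_m2, `/`),
    params$bmi_cap
  )
  delta_f <- params$f_gain_max * (1 - exp(-params$k_f * mvpa))
  delta_hr <- params$hr_drop_max * (1 - exp(-params$k_h * aerobic))

  list(delta_bmi = delta_bmi, delta_f = delta_f,
       calories = calories, delta_hr = delta_hr)
}

#' Predict health outcomes of a schedule for one student
#'
#' Applies the dose-response layer: per-session calories via
#' [calories_burned()] with the schedule's [effective_met()]; BMI reduction
#' from accumulated weekly energy expenditure over the model horizon (7700
#' kcal per kg convention, capped); fitness gain as a saturating exponential
#' in weekly moderate-to-vigorous hours; heart-rate reduction as a saturating
#' exponential in weekly aerobic hours.
#'
#' @param student A single cohort record (one-row data frame or list) with at
#'   least `weight_kg`, `height_cm`, `age`, `sex`.
#' @param sched A [schedule()].
#' @param params A [response_params()].
#' @return An `outcome_vector`: list with `delta_bmi` (kg/m^2), `delta_f`
#'   (points), `calories` (kcal/session), `delta_hr` (bpm).
#' @export
predict_outcomes <- function(student, sched, params = response_params()) {
  if (!inherits(sched, "pe_schedule")) {
    stop_config("predict_outcomes: `sched` must be a pe_schedule")
  }
  student <- as.data.frame(student[c("weight_kg", "height_cm", "age", "sex")])
  D <- schedule_to_row(sched)
  oc <- outcome_components(student, D, params)
  structure(
    list(delta_bmi = oc$delta_bmi[1, 1], delta_f = oc$delta_f[1],
         calories = oc$calories[1, 1], delta_hr = oc$delta_hr[1]),
    class = "outcome_vector"
  )
}

# one-row decoded matrix from a schedule object
schedule_to_row <- function(sched) {
  matrix(
    c(sched$t_session, sched$n_sessions, sched$activity_mix,
      sched$intensity_mix),
    nrow = 1,
    dimnames = list(NULL, c("t_session", "n_sessions",
                            paste0("a_", ACTIVITIES),
                            paste0("i_", INTENSITIES)))
  )
}

scale_metric <- function(x, bounds) {
  clamp((x - bounds[1]) / (bounds[2] - bounds[1]), 0, 1)
}

#' Weighted multi-metric fitness score
#'
#' Min-max scales each outcome metric to the unit interval by its decision-space bounds
#' (clipping outside values) and combines them as
#' `w1 * dBMI' + w2 * dF' + w3 * Cal' + w4 * dHR'`. The result always lies in
#' `[0, 1]`.
#'
#' @param outcomes An `outcome_vector` (or list with `delta_bmi`, `delta_f`,
#'   `calories`, `delta_hr`).
#' @param weights A [fitness_weights()].
#' @param norms A [metric_norms()].
#' @return A dimensionless score in `[0, 1]`.
#' @export
weighted_fitness <- function(outcomes, weights = fitness_weights(),
                             norms = metric_norms()) {
  weights$w1 * scale_metric(outcomes$delta_bmi, norms$delta_bmi) +
    weights$w2 * scale_metric(outcomes$delta_f, norms$delta_f) +
    weights$w3 * scale_metric(outcomes$calories, norms$calories) +
    weights$w4 * scale_metric(outcomes$delta_hr, norms$delta_hr)
}

# fitness of K decoded candidates against a whole cohort (vectorized core)
cohort_fitness_matrix <- function(cohort, D, weights, params, norms) {
  oc <- outcome_components(cohort, D, params)
  per_student <-
    weights$w1 * scale_metric(oc$delta_bmi, norms$delta_bmi) +
    weights$w3 * scale_metric(oc$calories, norms$calories)
  shared <-
    weights$w2 * scale_metric(oc$delta_f, norms$delta_f) +
    weights$w4 * scale_metric(oc$delta_hr, norms$delta_hr)
  colMeans(per_student) + shared
}

#' Cohort-level fitness of a schedule
#'
#' The objective value of a candidate schedule: the mean of
#' [weighted_fitness()] over all students in the cohort (per-student scores
#' are computed first, then averaged, which matters because the response
#' model is nonlinear in student anthropometrics).
#'
#' @param cohort A `pe_cohort` data frame (non-empty, complete
#'   `weight_kg`/`height_cm`/`age`/`sex`).
#' @param sched A [schedule()].
#' @param weights A [fitness_weights()].
#' @param params A [response_params()].
#' @param norms A [metric_norms()].
#' @return A single score in `[0, 1]`.
#' @export
cohort_fitness <- function(cohort, sched, weights = fitness_weights(),
                           params = response_params(), norms = metric_norms()) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) {
    stop_config("cohort_fitness: `cohort` must be a non-empty data frame")
  }
  cohort_fitness_matrix(cohort, schedule_to_row(sched), weights, params, norms)
}

#' Build a vectorized schedule objective from a cohort
#'
#' Returns a function mapping a decoded candidate matrix (rows = candidate
#' schedules, columns `t_session`, `n_sessions`, activity and intensity
#' shares) to the vector of cohort-mean weighted fitness scores. This is the
#' objective maximized by the optimizers. The returned function carries an
#' `outcome_fn` attribute that computes the cohort-mean outcome vector of a
#' single decoded candidate, used to fill `outcome_summary` in run results.
#'
#' @inheritParams cohort_fitness
#' @return A vectorized objective function.
#' @export
schedule_objective <- function(cohort, weights = fitness_weights(),
                               params = response_params(),
                               norms = metric_norms()) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) {
    stop_config("schedule_objective: `cohort` must be a non-empty data frame")
  }
  need <- c("weight_kg", "height_cm", "age", "sex")
  if (anyNA(cohort[, need])) {
    stop_config("schedule_objective: cohort has missing anthropometrics; ",
                "preprocess it first")
  }
  cohort <- cohort[, need]
  f <- function(D) cohort_fitness_matrix(cohort, D, weights, params, norms)
  attr(f, "outcome_fn") <- function(d_row) {
    oc <- outcome_components(cohort, matrix(d_row, nrow = 1,
                                            dimnames = list(NULL, names(d_row))),
                             params)
    list(delta_bmi = mean(oc$delta_bmi), delta_f = oc$delta_f[1],
         calories = mean(oc$calories), delta_hr = oc$delta_hr[1])
  }
  f
}
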