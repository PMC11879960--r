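test_that("basal metabolic rate matches hand arithmetic", {
  expect_equal(bmr(70, 175, 30, "male"), 1648.75)
  expect_equal(bmr(55, 160, 12, "female"), 1329)
  # sex constants differ by exactly 166
  expect_equal(bmr(60, 165, 14, "male") - bmr(60, 165, 14, "female"), 166)
  expect_error(bmr(-1, 160, 12, "female"), "positive")
  expect_error(bmr(60, 160, 12, "unknown"), "sex")
})

test_that("caloric expenditure matches hand arithmetic", {
  expect_equal(calories_burned(8, 50, 0.75, 1329), 698.7)
  expect_equal(calories_burned(8, 50, 0, 1329), 0)
  expect_equal(calories_burned(6, 40, 1.5, 0), 6 * 40 * 1.5)
  expect_error(calories_burned(-1, 50, 1, 1000), "non-negative")
})

test_that("effective MET is the mix-weighted table average", {
  params <- response_params()
  pure <- schedule(3, 1, c(1, 0, 0, 0, 0), c(0, 0, 1))
  expect_equal(effective_met(pure, params),
               params$met_table["aerobic", "vigorous"])
  uniform <- schedule(3, 1, rep(0.2, 5), rep(1 / 3, 3))
  expect_equal(effective_met(uniform, params), mean(params$met_table))
  # any valid mix is a convex combination, bounded by the table range
  set.seed(3)
  for (i in 1:25) {
    a <- stats::rgamma(5, 1); a <- a / sum(a)
    p <- stats::rgamma(3, 1); p <- p / sum(p)
    m <- effective_met(schedule(2, 1, a, p), params)
    expect_gte(m, min(params$met_table))
    expect_lte(m, max(params$met_table))
  }
})

test_that("weekly and daily PE time follow the session product", {
  res <- optimal_pe_time(5, 1.5, 5)
  expect_equal(res$weekly_hours, 7.5)
  expect_equal(res$daily_hours, 1.5)
  expect_equal(optimal_pe_time(0, 2)$weekly_hours, 0)
  expect_equal(optimal_pe_time(0, 2)$daily_hours, 0)
  # linearity in session duration
  expect_equal(optimal_pe_time(4, 2, 6)$weekly_hours,
               2 * optimal_pe_time(4, 1, 6)$weekly_hours)
  expect_error(optimal_pe_time(5, 1, days_per_week = 4), "days_per_week")
})

test_that("predicted outcomes match an independent closed-form evaluation", {
  student <- list(weight_kg = 50, height_cm = 160, age = 12, sex = "male")
  params <- response_params()
  sched <- schedule(4, 1.5, c(0.5, 0.2, 0.1, 0.1, 0.1), c(0.2, 0.3, 0.5))
  out <- predict_outcomes(student, sched, params)

  # independent spreadsheet-style evaluation of the stated formulas
  met_exp <- 0
  mix_a <- c(aerobic = 0.5, strength = 0.2, team = 0.1, flexibility = 0.1,
             recreational = 0.1)
  mix_i <- c(low = 0.2, moderate = 0.3, vigorous = 0.5)
  for (a in names(mix_a)) {
    for (i in names(mix_i)) {
      met_exp <- met_exp + mix_a[[a]] * mix_i[[i]] * params$met_table[a, i]
    }
  }
  bmr_exp <- 10 * 50 + 6.25 * 160 - 5 * 12 + 5
  cal_exp <- met_exp * 50 * 1.5 * (1 + bmr_exp / 1000)
  weekly_kcal <- cal_exp * 4
  dbmi_exp <- min(params$bmi_cap, 12 * weekly_kcal / 7700 / 1.6^2)
  mvpa <- 4 * 1.5 * (0.3 + 0.5)
  df_exp <- params$f_gain_max * (1 - exp(-params$k_f * mvpa))
  aerobic_h <- 4 * 1.5 * 0.5
  dhr_exp <- params$hr_drop_max * (1 - exp(-params$k_h * aerobic_h))

  expect_equal(out$calories, cal_exp, tolerance = 1e-12)
  expect_equal(out$delta_bmi, dbmi_exp, tolerance = 1e-12)
  expect_equal(out$delta_f, df_exp, tolerance = 1e-12)
  expect_equal(out$delta_hr, dhr_exp, tolerance = 1e-12)
})

test_that("outcomes vanish without activity and saturate with unbounded activity", {
  student <- list(weight_kg = 50, height_cm = 160, age = 12, sex = "male")
  params <- response_params()
  # zero session duration: all four outcomes are zero
  D0 <- peopt:::schedule_to_row(schedule(3, 1, rep(0.2, 5), rep(1 / 3, 3)))
  D0[, "t_session"] <- 0
  oc0 <- peopt:::outcome_components(as.data.frame(student), D0, params)
  expect_equal(oc0$calories[1, 1], 0)
  expect_equal(oc0$delta_bmi[1, 1], 0)
  expect_equal(oc0$delta_f[1], 0)
  expect_equal(oc0$delta_hr[1], 0)
  # unbounded weekly hours: saturating responses approach their asymptotes
  Dinf <- D0
  Dinf[, "t_session"] <- 1e6
  ocinf <- peopt:::outcome_components(as.data.frame(student), Dinf, params)
  expect_equal(ocinf$delta_f[1], params$f_gain_max)
  expect_equal(ocinf$delta_hr[1], params$hr_drop_max)
  expect_equal(ocinf$delta_bmi[1, 1], params$bmi_cap)
})

test_that("outcomes are monotone in session duration up to their caps", {
  student <- list(weight_kg = 48, height_cm = 155, age = 13, sex = "female")
  params <- response_params()
  set.seed(17)
  for (i in 1:30) {
    a <- stats::rgamma(5, 1); a <- a / sum(a)
    p <- stats::rgamma(3, 1); p <- p / sum(p)
    n <- sample(1:7, 1)
    t1 <- stats::runif(1, 0.1, 3)
    t2 <- t1 + stats::runif(1, 0.01, 1)
    o1 <- predict_outcomes(student, schedule(n, t1, a, p), params)
    o2 <- predict_outcomes(student, schedule(n, t2, a, p), params)
    expect_gte(o2$calories, o1$calories)
    expect_gte(o2$delta_f, o1$delta_f)
    expect_gte(o2$delta_hr, o1$delta_hr)
    expect_gte(o2$delta_bmi, o1$delta_bmi) # non-decreasing up to the cap
  }
})

test_that("the weighted fitness function is an exact scalarization", {
  unit <- metric_norms(c(0, 1), c(0, 1), c(0, 1), c(0, 1))
  out <- list(delta_bmi = 0.5, delta_f = 0.2, calories = 1.0, delta_hr = 0.0)
  expect_equal(weighted_fitness(out, fitness_weights(), unit), 0.46)
  # boundary values of the scalarization
  norms <- metric_norms()
  lo <- list(delta_bmi = 0, delta_f = 0, calories = 0, delta_hr = 0)
  hi <- list(delta_bmi = 5, delta_f = 20, calories = 800, delta_hr = 10)
  expect_equal(weighted_fitness(lo, fitness_weights(), norms), 0)
  expect_equal(weighted_fitness(hi, fitness_weights(), norms), 1)
  # permutation symmetry of the dot product
  out2 <- list(delta_bmi = 0.2, delta_f = 0.5, calories = 1.0, delta_hr = 0.0)
  expect_equal(weighted_fitness(out, fitness_weights(0.4, 0.3, 0.2, 0.1), unit),
               weighted_fitness(out2, fitness_weights(0.3, 0.4, 0.2, 0.1), unit))
  # linearity in the weights
  w_a <- fitness_weights(0.4, 0.3, 0.2, 0.1)
  w_b <- fitness_weights(0.1, 0.2, 0.3, 0.4)
  w_mix <- fitness_weights(0.25, 0.25, 0.25, 0.25)
  expect_equal(
    weighted_fitness(out, w_mix, unit),
    0.5 * weighted_fitness(out, w_a, unit) +
      0.5 * weighted_fitness(out, w_b, unit)
  )
})

test_that("cohort fitness averages per-student scores", {
  cohort <- tiny_cohort(2, seed = 6)
  sched <- schedule(5, 1.5, c(0.4, 0.2, 0.2, 0.1, 0.1), c(0.2, 0.5, 0.3))
  f1 <- weighted_fitness(predict_outcomes(cohort[1, ], sched))
  f2 <- weighted_fitness(predict_outcomes(cohort[2, ], sched))
  expect_equal(cohort_fitness(cohort, sched), (f1 + f2) / 2)
  # single-student cohort equals that student's score
  expect_equal(cohort_fitness(cohort[1, ], sched), f1)
  # duplicating every student leaves the mean unchanged
  expect_equal(cohort_fitness(rbind(cohort, cohort), sched),
               cohort_fitness(cohort, sched))
  expect_error(cohort_fitness(cohort[0, ], sched), "non-empty")
})

test_that("invalid model parameters are rejected naming the field", {
  expect_error(fitness_weights(0.4, 0.3, 0.2, 0.2), "sum to 1")
  expect_error(fitness_weights(-0.1, 0.5, 0.4, 0.2), ">= 0")
  expect_error(response_params(bmi_cap = 0), "bmi_cap")
  bad_met <- default_met_table()
  bad_met[1, 1] <- 0.5
  expect_error(response_params(met_table = bad_met), "\\[1, 15\\]")
  expect_error(metric_norms(delta_bmi = c(2, 2)), "delta_bmi")
  expect_error(schedule(0, 1, rep(0.2, 5), rep(1 / 3, 3)), "n_sessions")
  expect_error(schedule(3, 1, rep(0.25, 5), rep(1 / 3, 3)), "activity_mix")
})

test_that("a vigorous aerobic hour for a median 14-year-old burns a plausible amount", {
  cohort <- generate_cohort(cohort_spec(n_students = 2000, seed = 42))
  sub <- cohort[cohort$age == 14, ]
  # representative student: median 14-year-old anthropometrics
  med <- list(weight_kg = stats::median(sub$weight_kg),
              height_cm = stats::median(sub$height_cm),
              age = 14, sex = "male")
  sched <- schedule(5, 1, c(1, 0, 0, 0, 0), c(0, 0, 1))
  out <- predict_outcomes(med, sched, response_params())
  expect_gte(out$calories, 250)
  expect_lte(out$calories, 450)
})
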