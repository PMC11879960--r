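# Synthetic student-cohort generation.
#
# The generator emulates the feature set of a school PE-program dataset:
# demographics (age 6-18, sex), anthropometrics (height, weight, BMI),
# baseline health markers (fitness score 0-100, resting heart rate), and the
# operational PE features (weekly PE time, session frequency, activity-mix
# proportions, intensity level, per-session caloric expenditure,
# instructor-to-student ratio, facility utilization). Heights follow a sex-
# and age-conditional piecewise-linear growth reference with additive noise;
# BMI is drawn from a right-skewed (log-normal factor) distribution whose
# mean increases with age; weight is derived as bmi * (height/100)^2 so the
# three anthropometrics are mutually consistent by construction.

#' @rdname generate_cohort
#' @format NULL
#' @export
COHORT_COLUMNS <- c(
  "id", "age", "sex", "height_cm", "weight_kg", "bmi", "fitness_score",
  "rhr_bpm", "pe_time_hr_wk", "session_frequency",
  "act_aerobic", "act_strength", "act_team", "act_flexibility",
  "act_recreational", "intensity_level",
  "caloric_expenditure_kcal", "instructor_ratio", "facility_utilization"
)

ACTIVITY_COLS <- c(
  "act_aerobic", "act_strength", "act_team", "act_flexibility",
  "act_recreational"
)

CATEGORICAL_COLS <- c("sex", "intensity_level")

NUMERIC_COLS <- setdiff(COHORT_COLUMNS, c("id", CATEGORICAL_COLS))

# Features eligible for missing-cell injection: everything except the record
# identifier, BMI (kept complete so each record retains an anthropometric
# anchor) and the compositional activity block (kept complete so activity
# proportions always form a simplex).
MISSING_ELIGIBLE <- setdiff(COHORT_COLUMNS, c("id", "bmi", ACTIVITY_COLS))

# Unbounded-ish continuous features eligible for outlier displacement.
# Integer-valued and compositional features are excluded by contract.
OUTLIER_ELIGIBLE <- c(
  "height_cm", "weight_kg", "bmi", "fitness_score", "rhr_bpm",
  "pe_time_hr_wk", "caloric_expenditure_kcal", "instructor_ratio",
  "facility_utilization"
)

# Continuous features screened by the record-wise IQR outlier filter.
# Activity proportions are bounded compositional quantities, so Tukey fences
# are not applied to them.
FILTER_FEATURES <- c(
  "age", "height_cm", "weight_kg", "bmi", "fitness_score", "rhr_bpm",
  "pe_time_hr_wk", "session_frequency", "caloric_expenditure_kcal",
  "instructor_ratio", "facility_utilization"
)

# Piecewise-linear growth reference: median standing height (cm) at integer
# ages 6..18, by sex (rounded growth-chart magnitudes).
HEIGHT_REFERENCE <- list(
  male = c(
    `6` = 118.0, `7` = 124.0, `8` = 130.0, `9` = 135.5, `10` = 140.5,
    `11` = 145.5, `12` = 152.0, `13` = 158.5, `14` = 164.5, `15` = 169.5,
    `16` = 172.5, `17` = 174.5, `18` = 175.5
  ),
  female = c(
    `6` = 117.0, `7` = 123.0, `8` = 128.5, `9` = 134.0, `10` = 140.0,
    `11` = 146.5, `12` = 152.5, `13` = 157.0, `14` = 159.5, `15` = 161.0,
    `16` = 162.0, `17` = 162.5, `18` = 163.0
  )
)

#' Specify a synthetic cohort
#'
#' Bundles and validates the knobs of the synthetic cohort generator.
#'
#' @param n_students Number of student records to generate (default 1360).
#' @param seed RNG seed for the whole generation (and injection) process.
#' @param missing_rate Fraction of cells per eligible feature to blank out
#'   (missing completely at random), in `[0, 0.5]`.
#' @param outlier_rate Fraction of cells per eligible numeric feature to
#'   displace into the far tails, in `[0, 0.5]`.
#' @param age_range Integer ages, inclusive, within `[6, 18]`.
#' @param sex_ratio Fraction of male students.
#' @param bmi_log_sd Log-scale standard deviation of the right-skewed BMI
#'   distribution.
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(n_students = 100, seed = 7)
#' cohort <- generate_cohort(spec)
cohort_spec <- function(n_students = 1360, seed = 1, missing_rate = 0,
                        outlier_rate = 0, age_range = c(6L, 18L),
                        sex_ratio = 0.5, bmi_log_sd = 0.13) {
  if (!is_count(n_students)) {
    stop_config("cohort_spec: `n_students` must be a single integer >= 1")
  }
  if (!is_count(seed, min = 0)) {
    stop_config("cohort_spec: `seed` must be a single non-negative integer")
  }
  for (nm in c("missing_rate", "outlier_rate")) {
    v <- get(nm)
    if (!is_number(v) || v < 0 || v > 0.5) {
      stop_config("cohort_spec: `", nm, "` must be in [0, 0.5]")
    }
  }
  if (length(age_range) != 2L || !all(age_range == floor(age_range)) ||
      age_range[1] < 6 || age_range[2] > 18 || age_range[1] > age_range[2]) {
    stop_config("cohort_spec: `age_range` must be integer bounds within [6, 18]")
  }
  if (!is_number(sex_ratio) || sex_ratio < 0 || sex_ratio > 1) {
    stop_config("cohort_spec: `sex_ratio` must be in [0, 1]")
  }
  if (!is_number(bmi_log_sd) || bmi_log_sd <= 0) {
    stop_config("cohort_spec: `bmi_log_sd` must be > 0")
  }
  structure(
    list(
      n_students = as.integer(n_students), seed = as.integer(seed),
      missing_rate = missing_rate, outlier_rate = outlier_rate,
      age_range = as.integer(age_range), sex_ratio = sex_ratio,
      bmi_log_sd = bmi_log_sd
    ),
    class = "cohort_spec"
  )
}

#' Generate a seeded synthetic student cohort
#'
#' Draws `n_students` records with all cohort features. Ages are uniform on
#' the spec range; heights come from a sex/age piecewise-linear growth
#' reference plus Gaussian noise; BMI is right-skewed with an age-increasing
#' mean and weight is derived from BMI and height, so
#' `bmi == weight / (height/100)^2` holds exactly on every generated record.
#' Per-session caloric expenditure is computed from the record's own activity
#' mix, intensity level, weight and basal metabolic rate via
#' [calories_burned()], keeping the feature self-consistent with the health
#' model. Missingness and outliers are injected afterwards when the spec
#' requests them.
#'
#' `COHORT_COLUMNS` is the fixed column order (and CSV header) of a cohort.
#'
#' @param spec A [cohort_spec()].
#' @return A `data.frame` of class `pe_cohort` with columns `COHORT_COLUMNS`.
#' @seealso [inject_missingness()], [inject_outliers()], [write_cohort_csv()]
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) {
    stop_config("generate_cohort: `spec` must be a cohort_spec object")
  }
  set.seed(spec$seed)
  n <- spec$n_students

  age <- sample(seq(spec$age_range[1], spec$age_range[2]), n, replace = TRUE)
  sex <- ifelse(stats::runif(n) < spec$sex_ratio, "male", "female")

  height <- vapply(seq_len(n), function(i) {
    HEIGHT_REFERENCE[[sex[i]]][[as.character(age[i])]]
  }, numeric(1)) + stats::rnorm(n, 0, 6)
  height <- clamp(height, 95, 200)

  bmi_mean <- 15.3 + 0.38 * (age - 6)
  bmi <- clamp(bmi_mean * exp(stats::rnorm(n, 0, spec$bmi_log_sd)), 12, 38)
  weight <- bmi * (height / 100)^2

  fitness <- clamp(stats::rnorm(n, 62, 13), 0, 100)
  rhr <- clamp(103 - 1.8 * age + stats::rnorm(n, 0, 7), 50, 120)

  pe_time <- clamp(stats::rnorm(n, 2.5, 0.8), 0.5, 6)
  sess <- sample(1:5, n, replace = TRUE, prob = c(0.1, 0.25, 0.3, 0.25, 0.1))

  act_alpha <- c(3, 2, 3, 1, 2)
  g <- matrix(stats::rgamma(n * 5, shape = rep(act_alpha, each = n)), nrow = n)
  act <- g / rowSums(g)

  intensity <- sample(c("low", "moderate", "vigorous"), n, replace = TRUE,
                      prob = c(0.25, 0.5, 0.25))

  # per-session energy expenditure consistent with the health model
  met_tab <- default_met_table()
  met <- vapply(seq_len(n), function(i) {
    sum(act[i, ] * met_tab[, intensity[i]])
  }, numeric(1))
  bmr_val <- bmr(weight, height, age, sex)
  cal <- calories_burned(met, weight, pe_time / sess, bmr_val)

  cohort <- data.frame(
    id = sprintf("S%05d", seq_len(n)),
    age = as.numeric(age),
    sex = sex,
    height_cm = height,
    weight_kg = weight,
    bmi = bmi,
    fitness_score = fitness,
    rhr_bpm = rhr,
    pe_time_hr_wk = pe_time,
    session_frequency = as.numeric(sess),
    act_aerobic = act[, 1],
    act_strength = act[, 2],
    act_team = act[, 3],
    act_flexibility = act[, 4],
    act_recreational = act[, 5],
    intensity_level = intensity,
    caloric_expenditure_kcal = cal,
    instructor_ratio = clamp(stats::rnorm(n, 25, 5), 8, 45),
    facility_utilization = stats::rbeta(n, 5, 2),
    stringsAsFactors = FALSE
  )
  class(cohort) <- c("pe_cohort", "data.frame")

  if (spec$outlier_rate > 0) {
    cohort <- inject_outliers(cohort, spec$outlier_rate,
                              seed = derive_seed(spec$seed, "outliers"))
  }
  if (spec$missing_rate > 0) {
    cohort <- inject_missingness(cohort, spec$missing_rate,
                                 seed = derive_seed(spec$seed, "missing"))
  }
  cohort
}

#' Validate the structural invariants of a cohort
#'
#' Checks column presence, BMI/weight/height consistency (to 1e-6, on records
#' where all three are present), activity proportions on the simplex, and the
#' documented feature ranges. Intended for generated (pre-injection) cohorts;
#' injected outliers deliberately violate these invariants.
#'
#' @param cohort A `pe_cohort` data frame.
#' @param tol Simplex-sum tolerance.
#' @return Invisibly `TRUE`; errors describe the first violated invariant.
#' @export
validate_cohort <- function(cohort, tol = 1e-9) {
  if (!is.data.frame(cohort) || !all(COHORT_COLUMNS %in% names(cohort))) {
    stop_config("validate_cohort: not a cohort data frame (missing columns)")
  }
  all3 <- stats::complete.cases(cohort[, c("bmi", "weight_kg", "height_cm")])
  if (any(all3)) {
    derived <- cohort$weight_kg[all3] / (cohort$height_cm[all3] / 100)^2
    if (max(abs(derived - cohort$bmi[all3])) > 1e-6) {
      stop_config("validate_cohort: bmi != weight/(height/100)^2 beyond 1e-6")
    }
  }
  act <- as.matrix(cohort[, ACTIVITY_COLS])
  full <- stats::complete.cases(act)
  if (any(full)) {
    if (min(act[full, ]) < 0 || max(abs(rowSums(act[full, , drop = FALSE]) - 1)) > tol) {
      stop_config("validate_cohort: activity proportions off the simplex")
    }
  }
  rng_ok <- function(x, lo, hi) all(x >= lo & x <= hi, na.rm = TRUE)
  if (!rng_ok(cohort$age, 6, 18)) stop_config("validate_cohort: age outside [6, 18]")
  if (!rng_ok(cohort$fitness_score, 0, 100)) {
    stop_config("validate_cohort: fitness_score outside [0, 100]")
  }
  if (!rng_ok(cohort$rhr_bpm, 50, 120)) {
    stop_config("validate_cohort: rhr_bpm outside [50, 120]")
  }
  invisible(TRUE)
}

#' Inject missing cells completely at random
#'
#' Blanks an exact `round(rate * n)` count of cells in every eligible feature
#' (all features except `id`, `bmi` and the activity-proportion block), so the
#' realized per-feature missing fraction matches `rate` up to rounding.
#'
#' @param cohort A `pe_cohort` data frame.
#' @param rate Fraction of cells per eligible feature, in `[0, 0.5]`.
#' @param seed RNG seed.
#' @return The cohort with `NA` cells.
#' @export
inject_missingness <- function(cohort, rate, seed = 1) {
  if (!is_number(rate) || rate < 0 || rate > 0.5) {
    stop_config("inject_missingness: `rate` must be in [0, 0.5]")
  }
  if (rate == 0) return(cohort)
  set.seed(seed)
  n <- nrow(cohort)
  k <- round(rate * n)
  for (feat in MISSING_ELIGIBLE) {
    idx <- sample.int(n, k)
    cohort[[feat]][idx] <- NA
  }
  cohort
}

#' Inject extreme outlier values into numeric features
#'
#' Displaces an exact `round(rate * n)` count of cells per eligible continuous
#' feature to at least 3 interquartile ranges beyond the feature median (well
#' outside the Tukey fences at 1.5 IQR), so a downstream IQR filter is
#' guaranteed to flag them on large cohorts. Categorical and integer-coded
#' features are untouched by contract. The displacement log is stored in
#' `attr(cohort, "outlier_log")` as a data frame with columns
#' `id`, `feature`, `original`, `injected`.
#'
#' @inheritParams inject_missingness
#' @param features Continuous features to displace; defaults to every
#'   eligible one. Requesting a categorical or integer-coded feature is an
#'   error (they are no-ops by contract and silently listing them would hide
#'   that).
#' @export
inject_outliers <- function(cohort, rate, seed = 1,
                            features = OUTLIER_ELIGIBLE) {
  if (!is_number(rate) || rate < 0 || rate > 0.5) {
    stop_config("inject_outliers: `rate` must be in [0, 0.5]")
  }
  bad <- setdiff(features, OUTLIER_ELIGIBLE)
  if (length(bad)) {
    stop_config("inject_outliers: feature(s) not eligible for outlier ",
                "injection: ", paste(bad, collapse = ", "))
  }
  if (rate == 0) return(cohort)
  set.seed(seed)
  n <- nrow(cohort)
  k <- round(rate * n)
  log <- attr(cohort, "outlier_log") %||%
    data.frame(id = character(), feature = character(),
               original = numeric(), injected = numeric(),
               stringsAsFactors = FALSE)
  for (feat in features) {
    x <- cohort[[feat]]
    med <- stats::median(x, na.rm = TRUE)
    iqr <- stats::IQR(x, na.rm = TRUE, type = 7)
    scale <- max(iqr, abs(med) * 0.1, 1)
    idx <- sample.int(n, k)
    sign <- ifelse(stats::runif(k) < 0.5, -1, 1)
    new_val <- med + sign * (3 * iqr + stats::runif(k, 0.5, 1.5) * scale)
    log <- rbind(log, data.frame(
      id = cohort$id[idx], feature = feat,
      original = x[idx], injected = new_val, stringsAsFactors = FALSE
    ))
    cohort[[feat]][idx] <- new_val
  }
  attr(cohort, "outlier_log") <- log
  cohort
}

#' Read and write cohort CSV files
#'
#' The on-disk format is one row per student with the fixed header
#' `COHORT_COLUMNS` and missing cells encoded as empty strings. Numeric cells
#' are written with 17 significant digits so a write/read round trip
#' reproduces every double exactly.
#'
#' @param cohort A `pe_cohort` data frame.
#' @param path File path.
#' @return `read_cohort_csv()` returns a `pe_cohort`; `write_cohort_csv()`
#'   returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- cohort
  for (col in NUMERIC_COLS) {
    v <- formatC(out[[col]], format = "g", digits = 17)
    v[is.na(out[[col]])] <- ""
    out[[col]] <- trimws(v)
  }
  for (col in CATEGORICAL_COLS) {
    out[[col]][is.na(out[[col]])] <- ""
  }
  utils::write.table(out[, COHORT_COLUMNS], path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_config("read_cohort_csv: file not found: ", path)
  if (file.size(path) == 0) stop_config("read_cohort_csv: empty file: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0 && ncol(raw) == 0) {
    stop_config("read_cohort_csv: empty file: ", path)
  }
  unknown <- setdiff(names(raw), COHORT_COLUMNS)
  if (length(unknown)) {
    stop_config("read_cohort_csv: unknown column(s): ",
                paste(unknown, collapse = ", "))
  }
  absent <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(absent)) {
    stop_config("read_cohort_csv: missing column(s): ",
                paste(absent, collapse = ", "))
  }
  for (col in NUMERIC_COLS) {
    v <- raw[[col]]
    v[v == ""] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad)) {
      stop_config("read_cohort_csv: non-numeric value in column '", col,
                  "', row ", bad[1], ": '", v[bad[1]], "'")
    }
    raw[[col]] <- num
  }
  for (col in CATEGORICAL_COLS) {
    raw[[col]][raw[[col]] == ""] <- NA
  }
  raw <- raw[, COHORT_COLUMNS]
  class(raw) <- c("pe_cohort", "data.frame")
  raw
}

#' @export
print.pe_cohort <- function(x, ...) {
  cat(sprintf("<pe_cohort> %d students, %d features\n", nrow(x), ncol(x) - 1L))
  miss <- sum(is.na(x))
  if (miss > 0) cat(sprintf("  missing cells: %d\n", miss))
  NextMethod()
}
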