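test_that("generated cohorts have the full feature set and hold their invariants", {
  cohort <- generate_cohort(cohort_spec(n_students = 1360, seed = 7))
  expect_equal(nrow(cohort), 1360)
  expect_identical(names(cohort), COHORT_COLUMNS)
  expect_true(validate_cohort(cohort))
  expect_equal(sum(is.na(cohort)), 0)
  # anthropometric consistency on every record
  expect_equal(cohort$bmi, cohort$weight_kg / (cohort$height_cm / 100)^2,
               tolerance = 1e-12)
})

test_that("generation is bit-reproducible for a fixed seed", {
  a <- generate_cohort(cohort_spec(n_students = 1, seed = 99))
  b <- generate_cohort(cohort_spec(n_students = 1, seed = 99))
  expect_identical(a, b)
  c1 <- generate_cohort(cohort_spec(n_students = 200, seed = 5,
                                    missing_rate = 0.1, outlier_rate = 0.05))
  c2 <- generate_cohort(cohort_spec(n_students = 200, seed = 5,
                                    missing_rate = 0.1, outlier_rate = 0.05))
  expect_identical(c1, c2)
})

test_that("large-sample moments track the spec targets", {
  spec <- cohort_spec(n_students = 2000, seed = 31, sex_ratio = 0.6)
  cohort <- generate_cohort(spec)
  # age uniform on 6..18: mean 12, sd sqrt((13^2 - 1)/12)
  se_age <- sqrt((13^2 - 1) / 12) / sqrt(2000)
  expect_lt(abs(mean(cohort$age) - 12), 3 * se_age)
  se_sex <- sqrt(0.6 * 0.4 / 2000)
  expect_lt(abs(mean(cohort$sex == "male") - 0.6), 3 * se_sex)
})

test_that("invalid cohort specs are rejected naming the offending field", {
  expect_error(cohort_spec(n_students = 0), "n_students")
  expect_error(cohort_spec(missing_rate = 0.6), "missing_rate")
  expect_error(cohort_spec(outlier_rate = -0.1), "outlier_rate")
  expect_error(cohort_spec(age_range = c(4, 18)), "age_range")
  expect_error(cohort_spec(sex_ratio = 1.2), "sex_ratio")
})

test_that("missingness injection hits the requested per-feature rate", {
  cohort <- tiny_cohort(1000, seed = 3)
  out <- inject_missingness(cohort, rate = 0.1, seed = 11)
  eligible <- setdiff(COHORT_COLUMNS,
                      c("id", "bmi", grep("^act_", COHORT_COLUMNS, value = TRUE)))
  for (feat in eligible) {
    frac <- mean(is.na(out[[feat]]))
    expect_gte(frac, 0.08)
    expect_lte(frac, 0.12)
  }
  # id and bmi are never blanked; activity proportions stay complete
  expect_equal(sum(is.na(out$id)), 0)
  expect_equal(sum(is.na(out$bmi)), 0)
  expect_equal(sum(is.na(out[, grep("^act_", names(out))])), 0)
  # rate 0 is the identity; out-of-range rates error
  expect_identical(inject_missingness(cohort, 0), cohort)
  expect_error(inject_missingness(cohort, 0.6), "rate")
})

test_that("injected outliers land beyond the clean cohort's Tukey fences", {
  cohort <- tiny_cohort(1000, seed = 8)
  out <- inject_outliers(cohort, rate = 0.05, seed = 21)
  log <- attr(out, "outlier_log")
  expect_equal(nrow(log), 50 * 9) # round(0.05 * 1000) per eligible feature
  n_outside <- 0
  for (feat in unique(log$feature)) {
    f <- iqr_filter(cohort[[feat]])$fences # fences on the pre-injection data
    vals <- log$injected[log$feature == feat]
    n_outside <- n_outside + sum(vals < f[1] | vals > f[2])
  }
  expect_gte(n_outside / nrow(log), 0.95)
  # categorical features are untouched by contract
  expect_identical(out$sex, cohort$sex)
  expect_identical(out$intensity_level, cohort$intensity_level)
  expect_identical(inject_outliers(cohort, 0), cohort)
  expect_error(inject_outliers(cohort, 0.51), "rate")
})

test_that("cohort CSV round trip preserves every field including missing cells", {
  cohort <- inject_missingness(tiny_cohort(60, seed = 13), 0.15, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(cohort, path)
  back <- read_cohort_csv(path)
  for (col in COHORT_COLUMNS) {
    expect_identical(is.na(back[[col]]), is.na(cohort[[col]]), label = col)
    expect_equal(back[[col]], cohort[[col]], tolerance = 0, label = col)
  }
})

test_that("malformed cohort CSV files are rejected with a precise message", {
  path <- withr::local_tempfile(fileext = ".csv")
  cohort <- tiny_cohort(5)
  write_cohort_csv(cohort, path)

  lines <- readLines(path)
  lines[1] <- sub("age", "age,mystery_col", lines[1])
  lines[2:6] <- sub(",", ",0,", lines[2:6])
  writeLines(lines, path)
  expect_error(read_cohort_csv(path), "mystery_col")

  write_cohort_csv(cohort, path)
  lines <- readLines(path)
  lines[3] <- sub("^(S[0-9]+,)[0-9]+", "\\1not_a_number", lines[3])
  writeLines(lines, path)
  expect_error(read_cohort_csv(path), "row 2.*age|age.*row 2")

  file.create(path2 <- withr::local_tempfile(fileext = ".csv"))
  expect_error(read_cohort_csv(path2), "empty")
})
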