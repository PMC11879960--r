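test_that("mean imputation fills gaps with the mean and touches nothing else", {
  expect_equal(impute_mean(c(1, 2, NA, 3)), c(1, 2, 2, 3))
  x <- c(5, NA, 7.5, NA, 1)
  out <- impute_mean(x)
  expect_equal(out[!is.na(x)], x[!is.na(x)])
  expect_equal(out[is.na(x)], rep(4.5, 2))
  expect_identical(impute_mean(c(1, 2, 3)), c(1, 2, 3))
  expect_error(impute_mean(c(NA_real_, NA_real_)), "all values missing")
})

test_that("mode imputation uses the majority with first-occurrence ties", {
  expect_equal(impute_mode(c("M", "F", NA, "M")), c("M", "F", "M", "M"))
  expect_equal(impute_mode(c("M", "F", NA)), c("M", "F", "M"))
  expect_equal(impute_mode(c("F", "M", NA)), c("F", "M", "F"))
  expect_identical(impute_mode(c("a", "b")), c("a", "b"))
  expect_error(impute_mode(c(NA, NA)), "all values missing")
})

test_that("imputation preserves non-missing cells on random series", {
  set.seed(42)
  for (rep in 1:50) {
    x <- stats::rnorm(50)
    x[sample(50, 10)] <- NA
    keep <- !is.na(x)
    expect_identical(impute_mean(x)[keep], x[keep])
  }
})

test_that("the IQR filter matches hand computations under the type-7 quantile rule", {
  res <- iqr_filter(c(1, 2, 3, 4, 100))
  expect_equal(res$flagged, 5L)
  expect_equal(res$fences, c(-1, 7))
  expect_equal(sort(c(res$kept, res$flagged)), 1:5)

  const <- iqr_filter(rep(3, 10))
  expect_length(const$flagged, 0)
  expect_equal(const$fences, c(3, 3))

  # k = 0 flags everything outside [Q1, Q3]
  x <- c(2, 9, 4, 7, 1, 5, 8, 3, 6, 10)
  res0 <- iqr_filter(x, k = 0)
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  expect_equal(sort(res0$flagged), which(x < q[1] | x > q[2]))

  expect_error(iqr_filter(c(1, 2, 3)), "length >= 4")
})

test_that("the IQR filter agrees with a brute-force oracle on random series", {
  set.seed(7)
  for (rep in 1:1000) {
    n <- sample(4:40, 1)
    x <- round(stats::rt(n, df = 3) * 10, 2)
    k <- sample(c(0.5, 1, 1.5, 3), 1)
    res <- iqr_filter(x, k)
    # oracle: interpolate order statistics directly, compare every point
    s <- sort(x)
    interp <- function(p) {
      h <- (n - 1) * p + 1
      lo <- floor(h)
      s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
    }
    q1 <- interp(0.25)
    q3 <- interp(0.75)
    flagged <- which(x < q1 - k * (q3 - q1) | x > q3 + k * (q3 - q1))
    expect_identical(res$flagged, flagged)
  }
})

test_that("min-max scaling maps bounds to the unit interval", {
  expect_equal(min_max_scale(5, 0, 10), 0.5)
  expect_equal(min_max_scale(0, 0, 10), 0)
  expect_equal(min_max_scale(10, 0, 10), 1)
  expect_warning(z <- min_max_scale(3, 3, 3), "degenerate")
  expect_equal(z, 0)
  expect_error(min_max_scale(1, 5, 2), "xmax")
})

test_that("one-hot encoding produces exact binary indicator rows", {
  m <- one_hot_encode(c("male", "female"), c("male", "female"))
  expect_equal(m[1, ], c(male = 1L, female = 0L))
  expect_equal(m[2, ], c(male = 0L, female = 1L))
  set.seed(1)
  v <- sample(letters[1:4], 30, replace = TRUE)
  enc <- one_hot_encode(v, letters[1:4])
  expect_equal(rowSums(enc), rep(1, 30))
  expect_identical(colnames(enc), letters[1:4])
  expect_error(one_hot_encode(c("a", "z"), c("a", "b")), "z")
})

test_that("a clean cohort passes through preprocessing unchanged except scaling", {
  cohort <- tiny_cohort(200, seed = 4)
  out <- preprocess_cohort(cohort)
  expect_equal(out$report$n_in, 200)
  expect_equal(sum(out$report$imputed_cells_by_feature), 0)
  expect_equal(out$report$n_in, out$report$n_out + nrow(unique(out$report$removed_records["id"])))
  # every numeric feature of the scaled view lies in [0, 1]
  num <- setdiff(names(out$scaled), c("id"))
  for (col in num) {
    expect_gte(min(out$scaled[[col]]), 0)
    expect_lte(max(out$scaled[[col]]), 1)
  }
  # one-hot columns present, categorical originals gone
  expect_true(all(c("sex_male", "sex_female", "intensity_level_low") %in%
                    names(out$scaled)))
  expect_false(any(c("sex", "intensity_level") %in% names(out$scaled)))
})

test_that("record-wise removal reconciles with the injection log", {
  cohort <- tiny_cohort(20, seed = 128)
  # confirm the fixture is naturally fence-clean before injection
  base <- preprocess_cohort(cohort)
  expect_equal(base$report$n_out, 20)

  injected <- inject_outliers(cohort, rate = 0.1, seed = 5,
                              features = "rhr_bpm")
  log <- attr(injected, "outlier_log")
  expect_equal(nrow(log), 2)
  out <- preprocess_cohort(injected)
  expect_setequal(unique(out$report$removed_records$id), unique(log$id))
  expect_equal(out$report$n_out, 20 - length(unique(log$id)))
})

test_that("replaying stored fences and scaling parameters is the identity", {
  cohort <- inject_missingness(tiny_cohort(300, seed = 9), 0.05, seed = 1)
  first <- preprocess_cohort(cohort)
  replay <- preprocess_cohort(first$clean, config = list(
    fences = first$report$fences,
    scaling_params = first$report$scaling_params
  ))
  expect_equal(replay$clean, first$clean)
  expect_equal(replay$scaled, first$scaled)
  expect_equal(replay$report$n_in, replay$report$n_out)
})

test_that("stage failures carry the stage name", {
  cohort <- tiny_cohort(10)
  cohort$fitness_score <- NA_real_
  expect_error(preprocess_cohort(cohort), "impute")
})
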