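# Data-refinement chain: mean/mode imputation, IQR (Tukey fence) record
# removal, min-max scaling and one-hot encoding, with full bookkeeping in a
# preprocess_report so every transform can be audited or replayed.

#' Impute missing numeric values with the mean
#'
#' Missing entries are replaced by the arithmetic mean of the non-missing
#' entries; non-missing entries are never altered.
#'
#' @param values Numeric vector, possibly with `NA`s.
#' @return The completed vector.
#' @export
#' @examples
#' impute_mean(c(1, 2, NA, 3)) # NA -> 2
impute_mean <- function(values) {
  if (!is.numeric(values)) stop_config("impute_mean: `values` must be numeric")
  if (all(is.na(values))) stop_config("impute_mean: all values missing, cannot impute")
  values[is.na(values)] <- mean(values, na.rm = TRUE)
  values
}

#' Impute missing categorical values with the mode
#'
#' Missing entries are replaced by the most frequent category. Ties are broken
#' by first occurrence order in the series.
#'
#' @param values Character (or factor) vector, possibly with `NA`s.
#' @return The completed vector.
#' @export
#' @examples
#' impute_mode(c("M", "F", NA, "M")) # NA -> "M"
impute_mode <- function(values) {
  values <- as.character(values)
  if (all(is.na(values))) stop_config("impute_mode: all values missing, cannot impute")
  seen <- unique(values[!is.na(values)]) # first-occurrence order
  counts <- vapply(seen, function(v) sum(values == v, na.rm = TRUE), numeric(1))
  values[is.na(values)] <- seen[which.max(counts)]
  values
}

#' Flag outliers with Tukey fences on the interquartile range
#'
#' Values below `Q1 - k * IQR` or above `Q3 + k * IQR` are flagged, with Q1
#' and Q3 computed by linear interpolation of order statistics
#' (`stats::quantile()` type 7, the documented quantile rule). `kept` and
#' `flagged` always partition the series indices.
#'
#' @param values Numeric vector of length >= 4 without missing values.
#' @param k Fence multiplier (default 1.5).
#' @return A list with integer `kept`, integer `flagged`, and numeric
#'   `fences = c(lower, upper)`.
#' @export
#' @examples
#' iqr_filter(c(1, 2, 3, 4, 100)) # flags 100, fences c(-1, 7)
iqr_filter <- function(values, k = 1.5) {
  if (!is.numeric(values) || length(values) < 4) {
    stop_config("iqr_filter: `values` must be numeric with length >= 4")
  }
  if (anyNA(values)) stop_config("iqr_filter: `values` contains missing entries")
  if (!is_number(k) || k < 0) stop_config("iqr_filter: `k` must be >= 0")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(q[1] - k * iqr, q[2] + k * iqr)
  flagged <- which(values < fences[1] | values > fences[2])
  list(kept = setdiff(seq_along(values), flagged), flagged = flagged,
       fences = fences)
}

#' Min-max scale a value to the unit interval
#'
#' Returns `(x - xmin) / (xmax - xmin)`. When `xmax == xmin` the feature is
#' degenerate: the function returns 0 and emits a warning.
#'
#' @param x Numeric value(s).
#' @param xmin,xmax Scaling bounds, `xmax >= xmin`.
#' @return Scaled value(s); in `[0, 1]` when `x` lies within the bounds.
#' @export
#' @examples
#' min_max_scale(5, 0, 10) # 0.5
min_max_scale <- function(x, xmin, xmax) {
  if (!is_number(xmin) || !is_number(xmax)) {
    stop_config("min_max_scale: `xmin` and `xmax` must be finite numbers")
  }
  if (xmax < xmin) stop_config("min_max_scale: `xmax` must be >= `xmin`")
  if (xmax == xmin) {
    warning("min_max_scale: degenerate feature (xmin == xmax), returning 0",
            call. = FALSE)
    return(rep(0, length(x)))
  }
  (x - xmin) / (xmax - xmin)
}

#' One-hot encode a categorical series
#'
#' Each value becomes a binary row with a single 1 in the column of its
#' category; column order equals `category_order`.
#'
#' @param values Character vector without missing values.
#' @param category_order Character vector of allowed categories; defaults to
#'   first-occurrence order of `values`.
#' @return A binary matrix, `length(values)` rows, one column per category.
#' @export
#' @examples
#' one_hot_encode(c("male", "female"), c("male", "female"))
one_hot_encode <- function(values, category_order = NULL) {
  values <- as.character(values)
  if (anyNA(values)) stop_config("one_hot_encode: `values` contains missing entries")
  if (is.null(category_order)) category_order <- unique(values)
  unseen <- setdiff(unique(values), category_order)
  if (length(unseen)) {
    stop_config("one_hot_encode: unseen category: ",
                paste(unseen, collapse = ", "))
  }
  m <- matrix(0L, nrow = length(values), ncol = length(category_order),
              dimnames = list(NULL, category_order))
  m[cbind(seq_along(values), match(values, category_order))] <- 1L
  m
}

#' Preprocess a cohort: impute, filter, scale, encode
#'
#' Runs the fixed stage order impute -> IQR filter -> min-max scale -> one-hot
#' encode. Imputation happens first so fences are computed on complete data;
#' outlier handling is record-wise (a record is removed when any screened
#' continuous feature falls outside its Tukey fences). Scaling parameters are
#' estimated on the post-filter cohort and stored in the report, and
#' previously stored fences/scaling parameters can be supplied through
#' `config` to replay the exact transform (which makes a second application
#' of the pipeline to its own `clean` output the identity).
#'
#' @param cohort A `pe_cohort` data frame (non-empty).
#' @param config List of options: `iqr_k` (fence multiplier, default 1.5),
#'   `filter_features` (continuous features screened by the filter),
#'   `categories` (named list of category orders for `sex` and
#'   `intensity_level`), and optional stored `fences` / `scaling_params`
#'   from a previous report.
#' @return A list with:
#'   * `clean`: imputed and filtered cohort in natural units,
#'   * `scaled`: the clean cohort min-max scaled and one-hot encoded,
#'   * `report`: a `preprocess_report` with imputation counts, removed
#'     records, fences, scaling parameters and category orders.
#' @export
preprocess_cohort <- function(cohort, config = list()) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) {
    stop_config("preprocess_cohort: `cohort` must be a non-empty data frame")
  }
  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop_config("preprocess_cohort [stage: ", stage, "]: ",
                  conditionMessage(e))
    })
  }
  iqr_k <- config$iqr_k %||% 1.5
  filter_features <- intersect(config$filter_features %||% FILTER_FEATURES,
                               names(cohort))
  categories <- config$categories %||% list(
    sex = c("male", "female"),
    intensity_level = c("low", "moderate", "vigorous")
  )
  num_cols <- intersect(NUMERIC_COLS, names(cohort))
  cat_cols <- intersect(names(categories), names(cohort))
  n_in <- nrow(cohort)

  # stage 1: imputation
  imputed <- integer(0)
  with_stage("impute", {
    for (col in num_cols) {
      miss <- sum(is.na(cohort[[col]]))
      if (miss > 0) {
        cohort[[col]] <- impute_mean(cohort[[col]])
        imputed[col] <- miss
      }
    }
    for (col in cat_cols) {
      miss <- sum(is.na(cohort[[col]]))
      if (miss > 0) {
        cohort[[col]] <- impute_mode(cohort[[col]])
        imputed[col] <- miss
      }
    }
  })

  # stage 2: record-wise IQR filter
  removed <- data.frame(id = character(), feature = character(),
                        stringsAsFactors = FALSE)
  fences <- config$fences %||% NULL
  with_stage("iqr_filter", {
    if (is.null(fences)) {
      fences <- lapply(stats::setNames(filter_features, filter_features),
                       function(col) iqr_filter(cohort[[col]], k = iqr_k)$fences)
    }
    drop <- logical(nrow(cohort))
    for (col in names(fences)) {
      if (!col %in% names(cohort)) next
      f <- fences[[col]]
      bad <- cohort[[col]] < f[1] | cohort[[col]] > f[2]
      if (any(bad)) {
        removed <- rbind(removed, data.frame(
          id = cohort$id[bad], feature = col, stringsAsFactors = FALSE
        ))
        drop <- drop | bad
      }
    }
    cohort <- cohort[!drop, , drop = FALSE]
  })
  if (nrow(cohort) == 0) {
    stop_config("preprocess_cohort [stage: iqr_filter]: every record removed")
  }

  # stage 3: min-max scaling (parameters from the post-filter cohort)
  scaling <- config$scaling_params %||% NULL
  scaled <- cohort
  with_stage("scale", {
    if (is.null(scaling)) {
      scaling <- lapply(stats::setNames(num_cols, num_cols), function(col) {
        c(xmin = min(cohort[[col]]), xmax = max(cohort[[col]]))
      })
    }
    for (col in names(scaling)) {
      if (!col %in% names(scaled)) next
      p <- scaling[[col]]
      scaled[[col]] <- suppressWarnings(min_max_scale(scaled[[col]], p[1], p[2]))
    }
  })

  # stage 4: one-hot encoding (replaces categorical columns)
  with_stage("encode", {
    for (col in cat_cols) {
      enc <- one_hot_encode(scaled[[col]], categories[[col]])
      colnames(enc) <- paste(col, colnames(enc), sep = "_")
      pos <- match(col, names(scaled))
      scaled <- cbind(
        scaled[, seq_len(pos - 1), drop = FALSE],
        as.data.frame(enc),
        scaled[, seq(pos + 1, length.out = ncol(scaled) - pos), drop = FALSE]
      )
    }
  })
  class(scaled) <- "data.frame"
  rownames(cohort) <- NULL
  rownames(scaled) <- NULL

  report <- structure(
    list(
      n_in = n_in, n_out = nrow(cohort),
      imputed_cells_by_feature = imputed,
      removed_records = removed,
      fences = fences,
      scaling_params = scaling,
      encoded_features = categories[cat_cols]
    ),
    class = "preprocess_report"
  )
  list(clean = cohort, scaled = scaled, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("<preprocess_report>\n")
  cat(sprintf("  records: %d in -> %d out (%d removed)\n",
              x$n_in, x$n_out, x$n_in - x$n_out))
  cat(sprintf("  imputed cells: %d across %d feature(s)\n",
              sum(x$imputed_cells_by_feature),
              length(x$imputed_cells_by_feature)))
  invisible(x)
}

#' Serialize a preprocess report to JSON
#'
#' @param report A `preprocess_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_preprocess_report <- function(report, path) {
  jsonlite::write_json(
    list(
      n_in = report$n_in, n_out = report$n_out,
      imputed_cells_by_feature = as.list(report$imputed_cells_by_feature),
      removed_records = report$removed_records,
      fences = report$fences,
      scaling_params = lapply(report$scaling_params, as.list),
      encoded_features = report$encoded_features
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
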