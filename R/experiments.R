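# Study drivers: convergence comparison across algorithms under a shared
# evaluation budget, replicate summaries with normal-approximation
# confidence intervals, fitness-weight sensitivity analysis, and per-metric
# algorithm ranking.

ALL_ALGORITHMS <- c("ga", "pso", "aco", "sa", "de", "abc")

SUMMARY_METRICS <- c("pe_time_hr_wk", "delta_bmi", "delta_f",
                     "calories_kcal_session", "delta_hr_bpm")

# one config per algorithm; enforce the fair-budget guard
resolve_configs <- function(config, algorithms) {
  if (inherits(config, "optimizer_config")) {
    return(stats::setNames(rep(list(config), length(algorithms)), algorithms))
  }
  if (is.list(config) && all(algorithms %in% names(config))) {
    cfgs <- lapply(config[algorithms], as_optimizer_config)
    budgets <- vapply(cfgs, function(cf) cf$population * cf$iterations,
                      numeric(1))
    if (length(unique(budgets)) > 1) {
      stop_config("experiments: mismatched evaluation budgets across ",
                  "algorithms (population x iterations must be equal for a ",
                  "fair comparison)")
    }
    return(cfgs)
  }
  stop_config("experiments: `config` must be an optimizer_config or a named ",
              "list with one config per algorithm")
}

run_metrics <- function(res) {
  o <- res$outcome_summary
  if (is.null(o)) {
    stop_config("experiments: objective must be built with ",
                "schedule_objective() so outcome summaries are available")
  }
  s <- res$best_schedule
  c(
    pe_time_hr_wk = s$n_sessions * s$t_session,
    delta_bmi = o$delta_bmi,
    delta_f = o$delta_f,
    calories_kcal_session = o$calories,
    delta_hr_bpm = o$delta_hr
  )
}

# continuous algorithms search the continuous space; ACO (and any grid
# method) needs the discretized view
space_for <- function(algorithm, space) {
  if (algorithm == "aco" && !is_discrete(space)) discretize_space(space)
  else space
}

#' Compare convergence of several optimizers
#'
#' Runs each requested algorithm on the same cohort, decision space and
#' evaluation budget (guarded: mismatched budgets are an error) for one or
#' more seeds, and returns the aligned best-so-far trajectories in long
#' format, ready for export or plotting.
#'
#' @param cohort A preprocessed `pe_cohort` (complete anthropometrics).
#' @param space A [decision_space()]. ACO uses [discretize_space()] defaults
#'   when the space is continuous.
#' @param config A shared [optimizer_config()], or a named per-algorithm list
#'   of configs with equal `population * iterations` budgets.
#' @param algorithms Subset of `"ga"`, `"pso"`, `"aco"`, `"sa"`, `"de"`,
#'   `"abc"`.
#' @param seeds Integer vector of run seeds.
#' @param weights,params,norms Passed to [schedule_objective()].
#' @return A data frame of class `pe_convergence` with columns `algorithm`,
#'   `seed`, `iteration`, `best_so_far`.
#' @export
convergence_experiment <- function(cohort, space = decision_space(),
                                   config = optimizer_config(),
                                   algorithms = ALL_ALGORITHMS,
                                   seeds = 1L,
                                   weights = fitness_weights(),
                                   params = response_params(),
                                   norms = metric_norms()) {
  algorithms <- match.arg(algorithms, ALL_ALGORITHMS, several.ok = TRUE)
  cfgs <- resolve_configs(config, algorithms)
  objective <- schedule_objective(cohort, weights, params, norms)
  out <- list()
  for (alg in algorithms) {
    for (s in seeds) {
      cfg <- cfgs[[alg]]
      cfg$seed <- as.integer(s)
      res <- run_optimizer(alg, objective, space_for(alg, space), cfg)
      out[[length(out) + 1L]] <- data.frame(
        algorithm = alg, seed = s,
        iteration = seq_along(res$trajectory),
        best_so_far = res$trajectory,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, out)
  class(out) <- c("pe_convergence", "data.frame")
  out
}

#' @export
plot.pe_convergence <- function(x, ...) {
  algs <- unique(x$algorithm)
  wide <- sapply(algs, function(a) {
    sub <- x[x$algorithm == a, ]
    tapply(sub$best_so_far, sub$iteration, mean)
  })
  graphics::matplot(wide, type = "l", lty = 1, lwd = 2,
                    xlab = "iteration", ylab = "best-so-far fitness", ...)
  graphics::legend("bottomright", legend = algs, lty = 1, lwd = 2,
                   col = seq_along(algs))
  invisible(x)
}

#' Replicate summary of algorithms across health metrics
#'
#' Runs each algorithm `n_replicates` times with distinct derived seeds and
#' reports, per algorithm and metric, the replicate mean and a
#' normal-approximation confidence half-width
#' (`z * sd / sqrt(n_replicates)`). Metrics are weekly PE hours of the best
#' schedule and the cohort-mean outcome vector at the best schedule (BMI
#' reduction, fitness gain, kcal/session, heart-rate reduction), plus the
#' best fitness itself.
#'
#' @inheritParams convergence_experiment
#' @param n_replicates Replicates per algorithm (>= 2).
#' @param confidence Confidence level (default 0.95).
#' @param seed Base seed from which replicate seeds are derived.
#' @param seeds Optional explicit replicate seeds (recycled per algorithm);
#'   overrides `seed`-derived ones.
#' @return A data frame of class `summary_table`: one row per algorithm with
#'   `<metric>_mean` and `<metric>_half` columns and a `best_fitness_mean`.
#' @export
summary_experiment <- function(cohort, space = decision_space(),
                               config = optimizer_config(),
                               algorithms = ALL_ALGORITHMS,
                               n_replicates = 10, confidence = 0.95,
                               seed = 1, seeds = NULL,
                               weights = fitness_weights(),
                               params = response_params(),
                               norms = metric_norms()) {
  if (!is_count(n_replicates, min = 2)) {
    stop_config("summary_experiment: `n_replicates` must be an integer >= 2")
  }
  if (!is_number(confidence) || confidence <= 0 || confidence >= 1) {
    stop_config("summary_experiment: `confidence` must be in (0, 1)")
  }
  algorithms <- match.arg(algorithms, ALL_ALGORITHMS, several.ok = TRUE)
  cfgs <- resolve_configs(config, algorithms)
  objective <- schedule_objective(cohort, weights, params, norms)
  z <- stats::qnorm((1 + confidence) / 2)

  rows <- lapply(algorithms, function(alg) {
    rep_seeds <- if (!is.null(seeds)) {
      rep_len(as.integer(seeds), n_replicates)
    } else {
      vapply(seq_len(n_replicates),
             function(r) derive_seed(seed, paste0(alg, "-replicate-", r)),
             integer(1))
    }
    M <- vapply(rep_seeds, function(s) {
      cfg <- cfgs[[alg]]
      cfg$seed <- s
      res <- run_optimizer(alg, objective, space_for(alg, space), cfg)
      c(run_metrics(res), best_fitness = res$best_fitness)
    }, numeric(length(SUMMARY_METRICS) + 1L))
    mu <- rowMeans(M)
    half <- z * apply(M, 1, stats::sd) / sqrt(n_replicates)
    row <- c(rbind(mu, half))
    names(row) <- paste0(rep(names(mu), each = 2), c("_mean", "_half"))
    data.frame(algorithm = alg, as.list(row), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_replicates") <- n_replicates
  attr(out, "confidence") <- confidence
  class(out) <- c("summary_table", "data.frame")
  out
}

#' @export
print.summary_table <- function(x, digits = 2, ...) {
  cat(sprintf("<summary_table> %d replicates, %.0f%% confidence\n",
              attr(x, "n_replicates"), 100 * attr(x, "confidence")))
  for (i in seq_len(nrow(x))) {
    cells <- vapply(SUMMARY_METRICS, function(mn) {
      sprintf("%s %.*f +/- %.*f", mn, digits, x[i, paste0(mn, "_mean")],
              digits, x[i, paste0(mn, "_half")])
    }, character(1))
    cat(sprintf("  %-4s %s\n", x$algorithm[i], paste(cells, collapse = " | ")))
  }
  invisible(x)
}

#' Rank algorithms per metric
#'
#' Every summary metric is oriented so that larger is better (more weekly PE
#' time, larger reductions, more energy expenditure), so rank 1 goes to the
#' largest mean. Ties are broken alphabetically by algorithm name.
#'
#' @param summary A [summary_experiment()] result.
#' @return A data frame with one row per algorithm and one rank column per
#'   metric.
#' @export
rank_algorithms <- function(summary) {
  if (!inherits(summary, "summary_table")) {
    stop_config("rank_algorithms: `summary` must be a summary_table")
  }
  cols <- paste0(SUMMARY_METRICS, "_mean")
  if (anyNA(summary[, cols])) {
    stop_config("rank_algorithms: summary table has missing cells")
  }
  out <- data.frame(algorithm = sort(summary$algorithm),
                    stringsAsFactors = FALSE)
  for (mn in SUMMARY_METRICS) {
    v <- summary[[paste0(mn, "_mean")]]
    ord <- order(-v, summary$algorithm)
    rk <- integer(length(v))
    rk[ord] <- seq_along(v)
    out[[paste0(mn, "_rank")]] <-
      rk[match(out$algorithm, summary$algorithm)]
  }
  out
}

#' Sensitivity of optimized outcomes to the BMI-reduction weight
#'
#' Perturbs the first fitness weight by each relative `perturbation`
#' (`w1 <- w1 * (1 + delta)`, remaining weights rescaled proportionally so
#' the weights still sum to one), re-runs the same algorithm with the same
#' seed at each weight setting, and reports, per perturbation: a BMI
#' priority index (100 x optimized cohort-mean BMI reduction relative to
#' baseline), caloric expenditure (kcal/session), a fitness-score index
#' (defined analogously on the fitness gain), and heart-rate reduction
#' (bpm). The 0% row is the baseline itself, so its indices are exactly 100.
#'
#' @inheritParams convergence_experiment
#' @param perturbations Relative weight changes, each > -1 (default +/- 5%).
#' @param algorithm Algorithm used throughout (default `"aco"`).
#' @param seed Seed shared by the baseline and perturbed runs.
#' @return A data frame of class `sensitivity_report` with columns
#'   `weight_change_pct`, `bmi_priority_index`, `caloric_expenditure_kcal`,
#'   `fitness_score_index`, `hr_reduction_bpm`.
#' @export
sensitivity_experiment <- function(cohort, space = decision_space(),
                                   config = optimizer_config(),
                                   perturbations = c(-0.05, 0.05),
                                   algorithm = "aco", seed = 1,
                                   weights = fitness_weights(),
                                   params = response_params(),
                                   norms = metric_norms()) {
  if (any(perturbations <= -1)) {
    stop_config("sensitivity_experiment: perturbations must be > -100%")
  }
  algorithm <- match.arg(algorithm, ALL_ALGORITHMS)
  cfg <- as_optimizer_config(config)
  cfg$seed <- as.integer(seed)
  sp <- space_for(algorithm, space)

  run_at <- function(w) {
    objective <- schedule_objective(cohort, w, params, norms)
    run_metrics(run_optimizer(algorithm, objective, sp, cfg))
  }
  base <- run_at(weights)

  perturb_weights <- function(delta) {
    w1 <- weights$w1 * (1 + delta)
    if (w1 >= 1) {
      stop_config("sensitivity_experiment: perturbed w1 reaches 1; remaining ",
                  "weights cannot be renormalized")
    }
    rest <- (1 - w1) / (1 - weights$w1)
    fitness_weights(w1, weights$w2 * rest, weights$w3 * rest,
                    weights$w4 * rest)
  }

  deltas <- sort(unique(c(perturbations, 0)))
  rows <- lapply(deltas, function(d) {
    m <- if (d == 0) base else run_at(perturb_weights(d))
    data.frame(
      weight_change_pct = 100 * d,
      bmi_priority_index = 100 * m[["delta_bmi"]] / base[["delta_bmi"]],
      caloric_expenditure_kcal = m[["calories_kcal_session"]],
      fitness_score_index = 100 * m[["delta_f"]] / base[["delta_f"]],
      hr_reduction_bpm = m[["delta_hr_bpm"]]
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "algorithm") <- algorithm
  class(out) <- c("sensitivity_report", "data.frame")
  out
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> algorithm: %s\n", attr(x, "algorithm")))
  NextMethod()
}
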