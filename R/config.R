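# Run configuration: a single validated nested list drives the whole
# pipeline (cohort synthesis -> preprocessing -> optimization experiments),
# with defaults for every field, YAML/JSON loading, strict unknown-key
# rejection, and an artifact-writing pipeline driver.

#' Default run configuration
#'
#' The full nested configuration with every default filled in: cohort
#' synthesis settings, preprocessing options, decision-space bounds, fitness
#' weights, dose-response parameters, metric normalization bounds, optimizer
#' budget and hyperparameters, and experiment settings.
#'
#' @return A nested list of class `run_config`.
#' @export
default_config <- function() {
  met <- default_met_table()
  structure(
    list(
      seed = 1L,
      tasks = c("synth", "preprocess", "compare", "sensitivity"),
      cohort = list(
        n_students = 500L, missing_rate = 0, outlier_rate = 0,
        age_range = c(6L, 18L), sex_ratio = 0.5, bmi_log_sd = 0.13
      ),
      preprocess = list(iqr_k = 1.5),
      space = list(
        t_bounds = c(0.5, 2), n_bounds = c(1L, 7L), t_max_weekly = 10
      ),
      weights = list(w1 = 0.4, w2 = 0.3, w3 = 0.2, w4 = 0.1),
      response = list(
        horizon_weeks = 12, kcal_per_kg_fat = 7700, bmi_cap = 5,
        f_gain_max = 20, k_f = 0.15, hr_drop_max = 10, k_h = 0.2,
        met_table = lapply(
          stats::setNames(ACTIVITIES, ACTIVITIES),
          function(a) as.list(met[a, ])
        )
      ),
      norms = list(
        delta_bmi = c(0, 5), delta_f = c(0, 20), calories = c(0, 800),
        delta_hr = c(0, 10)
      ),
      optimizer = list(
        population = 30L, iterations = 200L, cache = FALSE,
        ga = list(pc = 0.9, pm = 0.1, sigma = 0.1, tournament = 3),
        pso = list(w = 0.7, c1 = 1.5, c2 = 1.5, vclamp = 0.5),
        aco = list(alpha = 1, beta = 1, rho = 0.1, Q = 1, tau0 = 1,
                   tau_min = 1e-9),
        sa = list(t0 = 1, gamma = 0.95, step = 0.15),
        de = list(f = 0.5, cr = 0.9),
        abc = list(limit = 20)
      ),
      experiments = list(
        algorithms = c("ga", "pso", "aco", "sa", "de", "abc"),
        replicates = 10L, confidence = 0.95,
        perturbations = c(-0.05, 0.05),
        sensitivity_algorithm = "aco",
        convergence_seeds = 1L
      )
    ),
    class = "run_config"
  )
}

# recursive strict merge: unknown keys rejected with a nearest-match hint
merge_config <- function(template, user, path = character()) {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(template))
  if (length(unknown)) {
    key <- unknown[1]
    near <- names(template)[which.min(utils::adist(key, names(template)))]
    where <- if (length(path)) paste0(" in `", paste(path, collapse = "$"), "`")
             else ""
    stop_config("config: unknown key `", key, "`", where,
                "; did you mean `", near, "`?")
  }
  for (nm in names(user)) {
    template[[nm]] <- if (is.list(template[[nm]]) && is.list(user[[nm]])) {
      merge_config(template[[nm]], user[[nm]], c(path, nm))
    } else {
      user[[nm]]
    }
  }
  template
}

# instantiate (and thereby validate) every typed object a config describes
config_objects <- function(config) {
  met <- default_met_table()
  for (a in ACTIVITIES) {
    for (i in INTENSITIES) met[a, i] <- config$response$met_table[[a]][[i]]
  }
  resp <- config$response
  list(
    spec = cohort_spec(
      n_students = config$cohort$n_students,
      seed = derive_seed(config$seed, "synth"),
      missing_rate = config$cohort$missing_rate,
      outlier_rate = config$cohort$outlier_rate,
      age_range = config$cohort$age_range,
      sex_ratio = config$cohort$sex_ratio,
      bmi_log_sd = config$cohort$bmi_log_sd
    ),
    space = decision_space(
      t_bounds = config$space$t_bounds,
      n_bounds = config$space$n_bounds,
      t_max_weekly = config$space$t_max_weekly
    ),
    weights = fitness_weights(config$weights$w1, config$weights$w2,
                              config$weights$w3, config$weights$w4),
    params = response_params(
      horizon_weeks = resp$horizon_weeks, met_table = met,
      kcal_per_kg_fat = resp$kcal_per_kg_fat, bmi_cap = resp$bmi_cap,
      f_gain_max = resp$f_gain_max, k_f = resp$k_f,
      hr_drop_max = resp$hr_drop_max, k_h = resp$k_h
    ),
    norms = metric_norms(
      delta_bmi = config$norms$delta_bmi, delta_f = config$norms$delta_f,
      calories = config$norms$calories, delta_hr = config$norms$delta_hr
    ),
    opt = optimizer_config(
      population = config$optimizer$population,
      iterations = config$optimizer$iterations,
      cache = config$optimizer$cache,
      ga = config$optimizer$ga, pso = config$optimizer$pso,
      aco = config$optimizer$aco, sa = config$optimizer$sa,
      de = config$optimizer$de, abc = config$optimizer$abc
    )
  )
}

#' Load and validate a run configuration file
#'
#' Reads YAML (or JSON, by file extension), merges the file over
#' [default_config()], rejects unknown keys with a nearest-match suggestion,
#' and validates every nested block by instantiating its typed object
#' (weights, decision space, response parameters, optimizer settings). An
#' empty file yields the defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_config("load_config: file not found: ", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  user <- user %||% list()
  config <- merge_config(unclass(default_config()), user)
  class(config) <- "run_config"
  config_objects(config) # validate; errors name the offending block/field
  config
}

#' Write the effective configuration
#'
#' Serializes a `run_config` (defaults merged) to YAML so a run directory
#' records exactly the settings that produced it; the written file parses
#' back into an identical configuration.
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full pipeline and write artifacts
#'
#' Executes the configured stages in order: `synth` (cohort generation),
#' `preprocess` (imputation, IQR filter, scaling, encoding), `compare`
#' (replicate summary across algorithms, ranking, and convergence
#' trajectories) and `sensitivity` (fitness-weight sensitivity). Every stage
#' seed derives deterministically from the global `config$seed` via
#' [derive_seed()]. The output directory receives the effective
#' configuration, every stage artifact, and a `MANIFEST.json` recording
#' files, stage timings, seeds and completion; on a stage failure the
#' manifest is written with `complete: false` before the error propagates.
#'
#' @param config A `run_config` (see [load_config()], [default_config()]) or
#'   a plain options list merged over the defaults.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the stage results and artifact paths.
#' @export
run_pipeline <- function(config = default_config(), out_dir, quiet = TRUE) {
  if (!inherits(config, "run_config")) {
    config <- merge_config(unclass(default_config()), config)
    class(config) <- "run_config"
  }
  obj <- config_objects(config) # fail fast before any computation
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(files = character(), stages = list(), complete = FALSE,
                   seed = config$seed)
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "MANIFEST.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  add_file <- function(p) manifest$files <<- c(manifest$files, basename(p))
  results <- list()

  write_config(config, file.path(out_dir, "config.yaml"))
  add_file("config.yaml")

  stage <- function(name, fn) {
    if (!name %in% config$tasks) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({fn(); TRUE}, error = function(e) e)
    secs <- proc.time()[["elapsed"]] - t0
    if (!isTRUE(ok)) {
      manifest$stages[[name]] <<- list(status = "failed", seconds = secs)
      write_manifest()
      stop_config("run_pipeline [stage: ", name, "]: ", conditionMessage(ok))
    }
    manifest$stages[[name]] <<- list(status = "ok", seconds = secs)
    if (!quiet) message(sprintf("stage %s done in %.1fs", name, secs))
  }

  cohort <- NULL
  clean <- NULL

  stage("synth", function() {
    cohort <<- generate_cohort(obj$spec)
    write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
    add_file("cohort.csv")
    results$cohort <<- cohort
  })

  stage("preprocess", function() {
    if (is.null(cohort)) cohort <<- generate_cohort(obj$spec)
    pp <- preprocess_cohort(cohort, config$preprocess)
    clean <<- pp$clean
    write_cohort_csv(pp$clean, file.path(out_dir, "clean_cohort.csv"))
    write_preprocess_report(pp$report,
                            file.path(out_dir, "preprocess_report.json"))
    add_file("clean_cohort.csv")
    add_file("preprocess_report.json")
    results$preprocess <<- pp$report
  })

  need_cohort <- function() {
    if (is.null(clean)) {
      if (is.null(cohort)) cohort <<- generate_cohort(obj$spec)
      clean <<- preprocess_cohort(cohort, config$preprocess)$clean
    }
    clean
  }

  ex <- config$experiments
  stage("compare", function() {
    co <- need_cohort()
    summ <- summary_experiment(
      co, obj$space, obj$opt, algorithms = ex$algorithms,
      n_replicates = ex$replicates, confidence = ex$confidence,
      seed = derive_seed(config$seed, "summary"),
      weights = obj$weights, params = obj$params, norms = obj$norms
    )
    utils::write.csv(summ, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    ranking <- rank_algorithms(summ)
    utils::write.csv(ranking, file.path(out_dir, "ranking.csv"),
                     row.names = FALSE)
    traj <- convergence_experiment(
      co, obj$space, obj$opt, algorithms = ex$algorithms,
      seeds = vapply(seq_len(max(1L, ex$convergence_seeds)),
                     function(r) derive_seed(config$seed,
                                             paste0("convergence-", r)),
                     integer(1)),
      weights = obj$weights, params = obj$params, norms = obj$norms
    )
    utils::write.csv(traj, file.path(out_dir, "trajectories.csv"),
                     row.names = FALSE)
    for (f in c("summary.csv", "summary.json", "ranking.csv",
                "trajectories.csv")) add_file(f)
    results$summary <<- summ
    results$ranking <<- ranking
    results$trajectories <<- traj
  })

  stage("sensitivity", function() {
    co <- need_cohort()
    sens <- sensitivity_experiment(
      co, obj$space, obj$opt, perturbations = ex$perturbations,
      algorithm = ex$sensitivity_algorithm,
      seed = derive_seed(config$seed, "sensitivity"),
      weights = obj$weights, params = obj$params, norms = obj$norms
    )
    utils::write.csv(sens, file.path(out_dir, "sensitivity.csv"),
                     row.names = FALSE)
    jsonlite::write_json(sens, file.path(out_dir, "sensitivity.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    add_file("sensitivity.csv")
    add_file("sensitivity.json")
    results$sensitivity <<- sens
  })

  manifest$complete <- TRUE
  write_manifest()
  results$out_dir <- out_dir
  invisible(results)
}
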