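#' Pipeline configuration
#'
#' Collects every tunable of the simulate -> preprocess -> extract -> fit
#' pipeline in one validated object. All detector thresholds that the
#' method leaves open live here with their package defaults, so they are
#' visible and overridable in one place.
#'
#' @param out_dir output directory of the run.
#' @param n_subjects,n_weeks cohort size of the simulated study.
#' @param fs sampling rate, Hz.
#' @param cutoff low-pass cutoff, Hz (must be below `fs/2`).
#' @param alpha significance level of the feature gate.
#' @param rating_noise_sd rating noise of the simulated experts.
#' @param level_range week-1 impairment range across subjects.
#' @param week_trend per-week impairment decrease.
#' @param paper_mode gate features on the full dataset (see [loso_cv()]).
#' @param seed master seed; every stage derives from it.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, n_subjects = 4L, n_weeks = 4L,
                            fs = 100, cutoff = 45, alpha = 0.05,
                            rating_noise_sd = 0.05,
                            level_range = c(0.2, 0.8), week_trend = 0.05,
                            paper_mode = FALSE, seed = 1L) {
  check_positive(fs, "fs")
  check_positive(cutoff, "cutoff")
  if (cutoff >= fs / 2) {
    stop(sprintf(
      "config invalid: cutoff (%g Hz) must be below fs/2 (%g Hz)",
      cutoff, fs / 2
    ), call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) {
    stop("config invalid: alpha must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(
      out_dir = out_dir, n_subjects = as.integer(n_subjects),
      n_weeks = as.integer(n_weeks), fs = fs, cutoff = cutoff,
      alpha = alpha, rating_noise_sd = rating_noise_sd,
      level_range = level_range, week_trend = week_trend,
      paper_mode = paper_mode, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the full pipeline
#'
#' Simulates the cohort, writes every session to disk, reads them back,
#' re-derives task segments from the labeling sensor, extracts the feature
#' table, fits and cross-validates one capacity model per task class with
#' enough sessions, and writes features, per-task evaluations and the
#' pooled task-independent features. Reruns with the same config are
#' bit-identical; any stage failure halts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) list with `features`, `evaluations` (named list of
#'   `capacity_eval`), `pooled`, and the output paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
        conditionMessage(e)
      ), call. = FALSE)
    })
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  say("simulate: %d subjects x %d weeks", config$n_subjects, config$n_weeks)
  cohort <- stage("simulate", simulate_cohort(
    n_subjects = config$n_subjects, n_weeks = config$n_weeks,
    rating_noise_sd = config$rating_noise_sd,
    level_range = config$level_range, week_trend = config$week_trend,
    fs = config$fs, seed = config$seed
  ))
  sess_dir <- file.path(config$out_dir, "sessions")
  manifests <- stage("write", vapply(cohort$sessions, function(s) {
    write_session(s, file.path(
      sess_dir, sprintf("%s_w%d", s$subject_id, s$week)
    ))
  }, character(1)))

  say("preprocess + extract: %d sessions", length(manifests))
  features <- stage("extract", {
    rows <- purrr::map(manifests, function(mp) {
      s <- read_session(mp)
      iv <- detect_task_boundaries(s$traces$labeler)
      if (nrow(iv) != nrow(s$ratings)) {
        stop(sprintf(
          "%s: detected %d task intervals but manifest lists %d",
          mp, nrow(iv), nrow(s$ratings)
        ), call. = FALSE)
      }
      s$segments <- tibble::tibble(
        task_class = s$ratings$task_class,
        side = s$ratings$side,
        start = iv$start, end = iv$end,
        start_s = iv$start_s, end_s = iv$end_s
      )
      inst <- extract_session_features(s, cutoff = config$cutoff)
      inst$target <- s$ratings$target
      inst
    })
    dplyr::bind_rows(rows)
  })
  feat_long <- features |>
    dplyr::mutate(feature = purrr::map(.data$features, \(f) {
      tibble::tibble(name = names(f), value = unname(f))
    })) |>
    dplyr::select(-"features") |>
    tidyr::unnest("feature")
  readr::write_csv(feat_long, file.path(config$out_dir, "features.csv"),
    progress = FALSE
  )

  say("fit: per-task capacity models")
  evals <- stage("fit", {
    out <- list()
    for (tc in unique(features$task_class)) {
      inst <- features[features$task_class == tc, ]
      n_sess <- length(unique(paste(inst$subject_id, inst$week)))
      if (n_sess < 3L) next
      out[[tc]] <- loso_cv(inst,
        task_class = tc, alpha = config$alpha,
        paper_mode = config$paper_mode
      )
    }
    out
  })
  report <- purrr::map(evals, function(ev) {
    list(
      task_class = ev$task_class,
      rmse = ev$metrics$rmse, r = ev$metrics$r,
      r_p_value = ev$metrics$r_p_value,
      n_instances = ev$metrics$n, n_sessions = ev$n_sessions,
      degenerate = ev$metrics$degenerate,
      retained_features = as.list(ev$model$weights[ev$model$retained]),
      p_values = as.list(ev$model$p_values[ev$model$retained]),
      predictions = ev$predictions
    )
  })
  jsonlite::write_json(report, file.path(config$out_dir, "evaluations.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )

  pooled <- stage("pool", pooled_generalization(features))
  readr::write_csv(pooled, file.path(config$out_dir, "pooled_features.csv"),
    progress = FALSE
  )

  cfg <- unclass(config)
  yaml::write_yaml(cfg, file.path(config$out_dir, "run_config.yaml"))

  invisible(list(
    features = features, evaluations = evals, pooled = pooled,
    paths = list(
      features = file.path(config$out_dir, "features.csv"),
      evaluations = file.path(config$out_dir, "evaluations.json"),
      pooled = file.path(config$out_dir, "pooled_features.csv")
    )
  ))
}
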