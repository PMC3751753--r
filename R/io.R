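# Session persistence: one delimited-text file per sensor (columns time_s,
# ax_g, ay_g, az_g, gx_dps, gy_dps, gz_dps), a YAML manifest (subject,
# week, sample rate, sensor -> file map, task list with ratings), a
# segments table and an optional ground-truth sidecar in JSON.

trace_columns <- c(
  "time_s", "ax_g", "ay_g", "az_g", "gx_dps", "gy_dps", "gz_dps"
)

#' Write a session recording to a directory
#'
#' @param session a `session_recording`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "session_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sensor_files <- list()
  for (p in names(session$traces)) {
    f <- paste0(p, ".csv")
    readr::write_csv(
      tibble::as_tibble(session$traces[[p]])[, trace_columns],
      file.path(dir, f), progress = FALSE
    )
    sensor_files[[p]] <- f
  }
  readr::write_csv(session$segments, file.path(dir, "segments.csv"),
    progress = FALSE
  )
  manifest <- list(
    subject_id = session$subject_id,
    week = session$week,
    fs = session$fs,
    sensors = sensor_files,
    segments_file = "segments.csv"
  )
  if (!is.null(session$instances)) {
    manifest$ratings <- purrr::map(seq_len(nrow(session$instances)), \(i) {
      list(
        task_class = session$instances$task_class[i],
        side = session$instances$side[i],
        target = session$instances$target[i]
      )
    })
    jsonlite::write_json(
      purrr::map(session$instances$truth, \(tr) rapply(
        tr, \(x) unname(x), how = "replace"
      )),
      file.path(dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    manifest$ground_truth_file = "ground_truth.json"
  }
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path, precision = 15L)
  invisible(path)
}

#' Read a session recording from its manifest
#'
#' Validates as it reads: every referenced sensor file must exist, all
#' sensors must share the sample count, placements must be known, and any
#' row with a non-finite value is rejected with its row index (never
#' silently dropped).
#'
#' @param manifest_path path to `manifest.yaml` written by
#'   [write_session()].
#' @return a `session_recording` (with an `instances` tibble when the
#'   manifest carries ratings; its features are re-extracted lazily by the
#'   pipeline, not stored on disk).
#' @export
read_session <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop(sprintf("manifest not found: %s", manifest_path), call. = FALSE)
  }
  man <- yaml::read_yaml(manifest_path)
  dir <- dirname(manifest_path)
  for (field in c("subject_id", "week", "fs", "sensors")) {
    if (is.null(man[[field]])) {
      stop(sprintf("manifest is missing field '%s'", field), call. = FALSE)
    }
  }

  traces <- list()
  for (p in names(man$sensors)) {
    if (!p %in% placement_levels()) {
      stop(sprintf("unknown placement '%s' in manifest", p), call. = FALSE)
    }
    f <- file.path(dir, man$sensors[[p]])
    if (!file.exists(f)) {
      stop(sprintf(
        "trace file for placement '%s' is missing: %s", p, f
      ), call. = FALSE)
    }
    df <- readr::read_csv(f,
      col_types = readr::cols(.default = readr::col_double()),
      progress = FALSE
    )
    if (!all(trace_columns %in% names(df))) {
      stop(sprintf("trace file %s lacks required columns", f),
        call. = FALSE
      )
    }
    bad <- which(!is.finite(rowSums(as.matrix(df[, trace_columns]))))
    if (length(bad) > 0L) {
      stop(sprintf(
        "non-finite values in %s at row(s) %s",
        f, paste(head(bad, 5L), collapse = ", ")
      ), call. = FALSE)
    }
    traces[[p]] <- imu_trace(
      as.matrix(df[, c("ax_g", "ay_g", "az_g")]),
      as.matrix(df[, c("gx_dps", "gy_dps", "gz_dps")]),
      fs = man$fs, placement = p
    )
  }
  lens <- vapply(traces, trace_length, integer(1))
  if (length(unique(lens)) > 1L) {
    stop(sprintf(
      "sensors disagree on sample count: %s",
      paste(sprintf("%s=%d", names(lens), lens), collapse = ", ")
    ), call. = FALSE)
  }

  segments <- NULL
  if (!is.null(man$segments_file)) {
    segments <- readr::read_csv(
      file.path(dir, man$segments_file),
      col_types = readr::cols(
        task_class = readr::col_character(),
        side = readr::col_character(),
        start = readr::col_integer(),
        end = readr::col_integer(),
        start_s = readr::col_double(),
        end_s = readr::col_double()
      ),
      progress = FALSE
    )
    n <- unique(lens)
    if (any(segments$start < 0 | segments$end > n |
              segments$start >= segments$end)) {
      stop("segments table contains intervals outside the traces",
        call. = FALSE
      )
    }
  }

  out <- structure(
    list(
      subject_id = man$subject_id,
      week = as.integer(man$week),
      fs = man$fs,
      traces = traces,
      segments = segments
    ),
    class = "session_recording"
  )
  if (!is.null(man$ratings)) {
    out$ratings <- dplyr::bind_rows(purrr::map(man$ratings, tibble::as_tibble))
  }
  out
}
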