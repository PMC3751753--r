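# Assembles whole recording sessions: per-sensor continuous traces with the
# task signals embedded into a quiescent background, the labeling-sensor
# trace bracketing every task, a segment table, and expert-style ratings
# generated as a known linear function of the extracted features.

#' Default rating-generation weights
#'
#' Ratings are generated as `clamp(w0 + sum_j w_j * f_j + noise, 0, 1)`
#' where `f_j` are the features extracted from the simulated traces. The
#' default weights reward spectral smoothness, rotation energy and
#' angular-velocity range and penalise long completion times (manual
#' tasks), penalise long and asymmetric steps (walking/stairs) and penalise
#' push-cycle lag (wheelchair), so that higher impairment maps to lower
#' ratings. Weights are on the raw feature scales; names match
#' [feature_names()] plus `"(Intercept)"`.
#'
#' @param task_class a task class string.
#' @return named numeric vector of generating weights.
#' @export
default_rating_weights <- function(task_class) {
  # completion time carries most of the rating (the dominant capacity
  # marker for speed-instructed tasks), with smoothness and angular-
  # velocity range as secondary contributors
  single <- c(
    "(Intercept)" = 0.78, TIME = -0.05, MI = 0, MIV = 0, DF = 0,
    SM = 0.25, ARE = 0, RANG = 0.001
  )
  kind <- task_kind(task_class)
  w <- switch(kind,
    single = single,
    bimanual = {
      half <- single[-1L] / 2
      c("(Intercept)" = 0.78,
        setNames(half, paste0(names(half), "_L")),
        setNames(half, paste0(names(half), "_R")))
    },
    gait = ,
    stairs = c(
      "(Intercept)" = 3.88, TIME = 0, MI = 0, MIV = 0, DF = 0,
      SM = 0.05, ARE = 0, RANG = 0,
      T_step_avg = -2.5, T_step_ratio = 0,
      T_stance_avg = 0, T_stance_ratio = 0
    ),
    wheelchair = c(
      "(Intercept)" = 0.95, TIME = 0, MI = 0, MIV = 0, DF = 0,
      SM = 0, ARE = 0, RANG = 0, ArmSync = -2.0
    )
  )
  stopifnot(identical(names(w)[-1L], feature_names(task_class)))
  w
}

rating_from_features <- function(features, weights, noise_sd = 0) {
  if (!identical(names(weights)[-1L], names(features))) {
    stop(sprintf(
      "rating weights do not match the feature layout (%d weights for %d features)",
      length(weights) - 1L, length(features)
    ), call. = FALSE)
  }
  raw <- weights[1L] + sum(weights[-1L] * features)
  noisy <- raw + rnorm(1L, 0, noise_sd)
  list(rating = min(max(noisy, 0), 1), rating_true = unname(raw))
}

#' Default task list of a simulated session
#'
#' Two single-handed card instances (one per hand), one bimanual ball
#' instance, a walking timed-up-and-go and a wheelchair timed-up-and-go.
#'
#' @return tibble with `task_class` and `side`.
#' @export
default_task_list <- function() {
  tibble::tribble(
    ~task_class, ~side,
    "cards", "left",
    "cards", "right",
    "ball", "both",
    "tug_walk", "n/a",
    "tug_wheelchair", "n/a"
  )
}

#' Simulate one weekly recording session
#'
#' Generates every task instance of `task_list` for the given subject
#' profile and week, embeds the task signals into continuous per-sensor
#' traces separated by quiescent gaps, synthesises the labeling-sensor
#' trace with a single rotation burst at each task start and a double
#' burst at each end, extracts the feature vector of every instance, and
#' generates its expert-style rating as a known linear function of those
#' features plus Gaussian noise (clamped to `[0, 1]`).
#'
#' @param profile an [impairment_profile()].
#' @param week week number (>= 1); impairment decreases with
#'   `profile$week_trend`.
#' @param task_list tibble with `task_class` and `side`
#'   (default [default_task_list()]).
#' @param rating_weights named list `task_class -> weight vector`;
#'   defaults to [default_rating_weights()] per class.
#' @param rating_noise_sd rating noise standard deviation.
#' @param subject_id subject identifier string.
#' @param fs sampling rate, Hz.
#' @param seed integer seed; the whole session is bit-deterministic.
#' @param gap_s quiescent gap between tasks, s.
#' @return a list of class `session_recording`: `subject_id`, `week`, `fs`,
#'   `traces` (named by placement, including `"labeler"`), `segments`
#'   (tibble `task_class`, `side`, `start`, `end`, `start_s`, `end_s`) and
#'   `instances` — a tibble of rated instances with a `features`
#'   list-column, the observed `target`, the noise-free `target_true`, and
#'   the per-task `truth` list-column from the generators.
#' @export
simulate_session <- function(profile, week = 1L,
                             task_list = default_task_list(),
                             rating_weights = NULL,
                             rating_noise_sd = 0.05,
                             subject_id = "S1", fs = 100, seed = 1L,
                             gap_s = 2.5) {
  check_positive(fs, "fs")
  stopifnot(all(c("task_class", "side") %in% names(task_list)))
  for (tc in unique(task_list$task_class)) task_kind(tc) # validates classes

  with_local_seed(seed, {
    task_seeds <- sample.int(.Machine$integer.max - 1L, nrow(task_list) + 1L)

    # generate each task instance
    sims <- purrr::map(seq_len(nrow(task_list)), function(i) {
      tc <- task_list$task_class[i]
      side <- task_list$side[i]
      kind <- task_kind(tc)
      if (kind == "single") {
        s <- simulate_manual_task(profile, tc,
          fs = fs, seed = task_seeds[i],
          side = side, week = week
        )
        pl <- trace_placement(s$trace)
        list(traces = setNames(list(s$trace), pl), truth = s$truth)
      } else if (kind == "bimanual") {
        sl <- simulate_manual_task(profile, tc,
          fs = fs, seed = task_seeds[i],
          side = "left", week = week
        )
        sr <- simulate_manual_task(profile, tc,
          fs = fs, seed = task_seeds[i] %% 1000000L + 7L,
          side = "right", week = week
        )
        # both hands act over one shared span: pad to equal length
        nmax <- max(trace_length(sl$trace), trace_length(sr$trace))
        pad <- function(tr) {
          extra <- nmax - trace_length(tr)
          if (extra == 0L) return(tr)
          q <- quiet_block(extra)
          imu_trace(
            rbind(accel_matrix(tr), q$accel),
            rbind(gyro_matrix(tr), q$gyro),
            fs, trace_placement(tr)
          )
        }
        list(
          traces = list(wrist_L = pad(sl$trace), wrist_R = pad(sr$trace)),
          truth = list(left = sl$truth, right = sr$truth)
        )
      } else if (kind %in% c("gait", "stairs")) {
        lev <- effective_level(profile, week)
        affected_left <- profile$side_affected == "left"
        base <- if (kind == "gait") 1.2 else 1.5
        slow <- base * (1 + 0.5 * lev)
        g <- simulate_gait(
          step_dur_left = if (affected_left) slow else base,
          step_dur_right = if (affected_left) base else slow,
          stance_frac = 0.6 + runif(1, -0.05, 0.05),
          n_steps = 8L, fs = fs, seed = task_seeds[i]
        )
        if (kind == "stairs") {
          names(g$traces) <- c("hip", "upper_leg_L", "upper_leg_R")
          for (p in names(g$traces)) attr(g$traces[[p]], "placement") <- p
        }
        g
      } else { # wheelchair
        lev <- effective_level(profile, week)
        simulate_wheelchair(
          cycle_dur = 1.0 * (1 + 0.2 * lev),
          lag_frac = min(0.45, 0.05 + 0.30 * lev),
          n_cycles = 6L, turn_dur = 3, fs = fs, seed = task_seeds[i]
        )
      }
    })

    # lay tasks on the session timeline
    placements <- unique(c(
      "wrist_L", "wrist_R", "hip", "foot_L", "foot_R",
      unlist(purrr::map(sims, ~ names(.x$traces)))
    ))
    lens <- vapply(sims, function(s) trace_length(s$traces[[1L]]), integer(1))
    gap_n <- round(gap_s * fs)
    starts <- cumsum(c(gap_n, head(lens + gap_n, -1L)))
    ends <- starts + lens
    n_total <- ends[length(ends)] + gap_n

    traces <- setNames(lapply(placements, function(p) {
      q <- quiet_block(n_total)
      acc <- q$accel
      gyr <- q$gyro
      for (i in seq_along(sims)) {
        tr <- sims[[i]]$traces[[p]]
        if (is.null(tr)) next
        idx <- seq.int(starts[i] + 1L, ends[i])
        acc[idx, ] <- accel_matrix(tr)
        gyr[idx, ] <- gyro_matrix(tr)
      }
      imu_trace(acc, gyr, fs, placement = p)
    }), placements)

    segments <- tibble::tibble(
      task_class = task_list$task_class,
      side = task_list$side,
      start = as.integer(starts),
      end = as.integer(ends),
      start_s = starts / fs,
      end_s = ends / fs
    )

    labeler <- simulate_labeling_trace(
      purrr::map(seq_along(starts), ~ c(starts[.x], ends[.x]) / fs),
      fs = fs, seed = task_seeds[length(task_seeds)],
      total_dur_s = n_total / fs
    )
    traces$labeler <- labeler

    session <- structure(
      list(
        subject_id = subject_id, week = as.integer(week), fs = fs,
        traces = traces, segments = segments
      ),
      class = "session_recording"
    )

    # features from the embedded traces; ratings linear in those features
    inst <- extract_session_features(session)
    ratings <- purrr::map(seq_len(nrow(inst)), function(i) {
      tc <- inst$task_class[i]
      w <- rating_weights[[tc]] %||NULL% default_rating_weights(tc)
      rating_from_features(inst$features[[i]], w, rating_noise_sd)
    })
    inst$target <- vapply(ratings, `[[`, numeric(1), "rating")
    inst$target_true <- vapply(ratings, `[[`, numeric(1), "rating_true")
    inst$truth <- purrr::map(sims, "truth")
    session$instances <- inst
    session
  })
}

`%||NULL%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf(
    "<session_recording> subject=%s week=%d fs=%g Hz, %d sensors, %d tasks\n",
    x$subject_id, x$week, x$fs, length(x$traces), nrow(x$segments)
  ))
  invisible(x)
}

#' Simulate a cohort of subjects over several weeks
#'
#' Subjects receive impairment levels spread over `level_range`, alternating
#' affected sides, and a recovery trend so that ratings improve over weeks.
#'
#' @param n_subjects number of subjects.
#' @param n_weeks weekly sessions per subject.
#' @param task_list per-session task list (default [default_task_list()]).
#' @param rating_noise_sd rating noise standard deviation.
#' @param level_range range of week-1 impairment levels across subjects.
#' @param week_trend per-week decrease of the impairment level.
#' @param fs sampling rate, Hz.
#' @param seed integer seed.
#' @return list with `sessions` (list of `session_recording`) and
#'   `instances` — all rated instances bound into one tibble.
#' @export
simulate_cohort <- function(n_subjects = 4L, n_weeks = 4L,
                            task_list = default_task_list(),
                            rating_noise_sd = 0.05,
                            level_range = c(0.2, 0.8),
                            week_trend = 0.05, fs = 100, seed = 1L) {
  stopifnot(n_subjects >= 1L, n_weeks >= 1L)
  with_local_seed(seed, {
    levels <- seq(level_range[1L], level_range[2L],
      length.out = n_subjects
    )
    seeds <- matrix(
      sample.int(.Machine$integer.max - 1L, n_subjects * n_weeks),
      n_subjects, n_weeks
    )
    sessions <- list()
    for (s in seq_len(n_subjects)) {
      prof <- impairment_profile(
        level = levels[s],
        side_affected = if (s %% 2L == 0L) "right" else "left",
        week_trend = week_trend
      )
      for (w in seq_len(n_weeks)) {
        sessions[[length(sessions) + 1L]] <- simulate_session(
          prof,
          week = w, task_list = task_list,
          rating_noise_sd = rating_noise_sd,
          subject_id = sprintf("S%d", s), fs = fs,
          seed = seeds[s, w]
        )
      }
    }
    instances <- dplyr::bind_rows(purrr::map(sessions, "instances"))
    list(sessions = sessions, instances = instances)
  })
}
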