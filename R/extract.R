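#' Task classes and their feature layouts
#'
#' Twelve task classes are recognised. Single-handed manual tasks (turn
#' cards, pick up small objects, stack dominos, use a key, nine-hole peg
#' test) yield 7 features from the performing wrist; bimanual tasks (lift
#' bigger objects, open/close a bottle, play ball) yield 14 (the left-wrist
#' block then the right-wrist block); timed-up-and-go walking and stair
#' climbing yield 11 (7 hip features plus 4 step/stance features from the
#' feet or upper legs); the wheelchair timed-up-and-go yields 8 (7 hip
#' features plus arm synchrony from both wrists).
#'
#' @return `task_classes()`: tibble with `task_class`, `kind`
#'   (`"single"`, `"bimanual"`, `"gait"`, `"stairs"`, `"wheelchair"`) and
#'   `n_features`.
#' @export
task_classes <- function() {
  tibble::tribble(
    ~task_class, ~kind, ~n_features,
    "cards", "single", 7L,
    "small_objects", "single", 7L,
    "dominos", "single", 7L,
    "key", "single", 7L,
    "nhpt", "single", 7L,
    "big_objects", "bimanual", 14L,
    "bottle", "bimanual", 14L,
    "ball", "bimanual", 14L,
    "tug_walk", "gait", 11L,
    "stairs_up", "stairs", 11L,
    "stairs_down", "stairs", 11L,
    "tug_wheelchair", "wheelchair", 8L
  )
}

task_kind <- function(task_class) {
  tc <- task_classes()
  k <- tc$kind[match(task_class, tc$task_class)]
  if (is.na(k)) stop(sprintf("unknown task class '%s'", task_class),
    call. = FALSE
  )
  k
}

#' @rdname task_classes
#' @param task_class a task class string.
#' @return `feature_names()`: character vector of feature names in layout
#'   order for that class.
#' @export
feature_names <- function(task_class) {
  base <- c("TIME", "MI", "MIV", "DF", "SM", "ARE", "RANG")
  switch(task_kind(task_class),
    single = base,
    bimanual = c(paste0(base, "_L"), paste0(base, "_R")),
    gait = ,
    stairs = c(base, "T_step_avg", "T_step_ratio",
               "T_stance_avg", "T_stance_ratio"),
    wheelchair = c(base, "ArmSync")
  )
}

# the seven magnitude-based features shared by every layout
core_features <- function(trace, fs) {
  amag <- magnitude(trace, "accel")
  mi <- movement_interval(amag, fs)
  # locomotion segments begin and end mid-activity (the label bursts
  # bracket the task exactly), so when no internal quiescent/active
  # contrast exists the completion time is the whole segment
  time_s <- if (isTRUE(mi$moved)) mi$time_s else nrow(trace) / fs
  c(
    TIME = time_s,
    MI = movement_intensity(accel_matrix(trace)),
    MIV = movement_intensity_variation(accel_matrix(trace)),
    DF = dominant_frequency(amag, fs),
    SM = as.numeric(smoothness(amag, fs)),
    ARE = average_rotation_energy(gyro_matrix(trace)),
    RANG = range_angular_velocity(gyro_matrix(trace))
  )
}

required_placements <- function(task_class, side = "n/a") {
  switch(task_kind(task_class),
    single = if (side == "left") "wrist_L" else "wrist_R",
    bimanual = c("wrist_L", "wrist_R"),
    gait = c("hip", "foot_L", "foot_R"),
    stairs = c("hip", "upper_leg_L", "upper_leg_R"),
    wheelchair = c("hip", "wrist_L", "wrist_R")
  )
}

#' Extract the feature vector of one task instance
#'
#' Dispatches on the task class: filters the relevant sensor windows with
#' the 45 Hz zero-phase low-pass, computes the seven magnitude features
#' (TIME, MI, MIV, DF, SM, ARE, RANG) from the performing wrist (single),
#' both wrists (bimanual, left block then right block) or the hip
#' (locomotion), and appends step/stance features (walking: feet; stairs:
#' upper legs) or arm synchrony over the straight-driving blocks
#' (wheelchair).
#'
#' @param session a `session_recording` (see [simulate_session()] /
#'   [read_session()]).
#' @param segment one row of the session's segment table: `task_class`,
#'   `side`, `start`, `end` (half-open, 0-based samples).
#' @param cutoff low-pass cutoff, Hz.
#' @return a named numeric vector in the layout of
#'   [feature_names()] for the task class.
#' @export
extract_task_features <- function(session, segment, cutoff = 45) {
  task_class <- segment$task_class
  side <- segment$side %||% "n/a"
  fs <- session$fs
  need <- required_placements(task_class, side)
  missing <- setdiff(need, names(session$traces))
  if (length(missing) > 0L) {
    stop(sprintf(
      "task '%s' requires placement(s) %s, absent from the session",
      task_class, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  win <- function(placement) {
    lowpass_trace(
      trace_window(session$traces[[placement]], segment$start, segment$end),
      cutoff = cutoff
    )
  }

  kind <- task_kind(task_class)
  if (kind == "single") {
    return(core_features(win(need), fs))
  }
  if (kind == "bimanual") {
    fl <- core_features(win("wrist_L"), fs)
    fr <- core_features(win("wrist_R"), fs)
    names(fl) <- paste0(names(fl), "_L")
    names(fr) <- paste0(names(fr), "_R")
    return(c(fl, fr))
  }

  hip <- core_features(win("hip"), fs)
  if (kind %in% c("gait", "stairs")) {
    left_p <- if (kind == "gait") "foot_L" else "upper_leg_L"
    right_p <- if (kind == "gait") "foot_R" else "upper_leg_R"
    ev_l <- detect_heel_strikes(magnitude(win(left_p), "accel"), fs)
    ev_r <- detect_heel_strikes(magnitude(win(right_p), "accel"), fs)
    gd <- gait_durations(ev_l, ev_r, fs)
    return(c(hip, unlist(gd[1L, ])))
  }

  # wheelchair: arm synchrony over straight-driving blocks of both wrists
  lmag <- magnitude(win("wrist_L"), "accel")
  rmag <- magnitude(win("wrist_R"), "accel")
  phases <- segment_drive_phases((lmag + rmag) / 2, fs)
  straight <- phases[phases$regime == "straight", ]
  sync <- arm_synchrony(lmag, rmag, fs, straight_segments = straight)
  c(hip, ArmSync = sync$armsync)
}

#' Extract features for every segment of a session
#'
#' @param session a `session_recording`.
#' @param cutoff low-pass cutoff, Hz.
#' @return tibble with one row per task instance: `subject_id`, `week`,
#'   `task_class`, `side`, `start`, `end` and a `features` list-column of
#'   named numeric vectors (layouts differ between task classes).
#' @export
extract_session_features <- function(session, cutoff = 45) {
  segs <- session$segments
  feats <- purrr::map(seq_len(nrow(segs)), function(i) {
    extract_task_features(session, segs[i, ], cutoff = cutoff)
  })
  tibble::tibble(
    subject_id = session$subject_id,
    week = session$week,
    task_class = segs$task_class,
    side = segs$side,
    start = segs$start,
    end = segs$end,
    features = feats
  )
}

#' Spread the features list-column into wide columns
#'
#' Only meaningful for instances sharing one task-class layout.
#'
#' @param instances tibble with a `features` list-column.
#' @return tibble with one numeric column per feature.
#' @export
features_wide <- function(instances) {
  mat <- do.call(rbind, instances$features)
  dplyr::bind_cols(
    dplyr::select(instances, -"features"),
    tibble::as_tibble(mat)
  )
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a
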