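# Synthetic IMU session generators. These define the study conditions the
# package is tested under: cyclic wrist movement whose duration, amplitude,
# spectral concentration and rotation range are driven by a latent
# impairment level; gait with programmable step/stance durations; wheelchair
# propulsion with a programmable bilateral push lag; and a labeling-sensor
# trace with single/double rotation bursts bracketing each task. Every
# generator returns full ground truth and is bit-deterministic given `seed`.

#' Impairment profile of a simulated subject
#'
#' @param level latent impairment in `[0, 1]` (0 = unimpaired) at week 1.
#' @param side_affected `"left"`, `"right"` or `"none"`.
#' @param week_trend non-negative per-week decrease of `level` (recovery
#'   over the course of rehabilitation).
#' @return a list of class `impairment_profile`.
#' @export
impairment_profile <- function(level, side_affected = c("none", "left", "right"),
                               week_trend = 0) {
  side_affected <- match.arg(side_affected)
  if (!is.numeric(level) || level < 0 || level > 1) {
    stop("`level` must lie in [0, 1]", call. = FALSE)
  }
  if (week_trend < 0) stop("`week_trend` must be >= 0", call. = FALSE)
  structure(
    list(level = level, side_affected = side_affected,
         week_trend = week_trend),
    class = "impairment_profile"
  )
}

#' @rdname impairment_profile
#' @param profile an `impairment_profile`.
#' @param week week number (>= 1).
#' @param side `"left"`, `"right"` or `"both"`: which body side is doing the
#'   work; the unaffected side retains a mild fraction of the impairment.
#' @return `effective_level()`: the impairment level in `[0, 1]` governing
#'   that side at that week.
#' @export
effective_level <- function(profile, week = 1L, side = "both") {
  lev <- min(max(profile$level - profile$week_trend * (week - 1L), 0), 1)
  if (profile$side_affected == "none" || side == "both") return(lev)
  if (side == profile$side_affected) lev else 0.15 * lev
}

# quiescent 6-channel block: gravity on z plus sensor noise
quiet_block <- function(n, noise_sd = 0.01, gyro_noise_sd = 1) {
  list(
    accel = cbind(
      rnorm(n, 0, noise_sd),
      rnorm(n, 0, noise_sd),
      1 + rnorm(n, 0, noise_sd)
    ),
    gyro = cbind(
      rnorm(n, 0, gyro_noise_sd),
      rnorm(n, 0, gyro_noise_sd),
      rnorm(n, 0, gyro_noise_sd)
    )
  )
}

jit <- function(x, frac) x * exp(runif(1, -frac, frac))

# base cycle rates (Hz) of the cyclic manual tasks
manual_base_freq <- function(task_class) {
  switch(task_class,
    cards = 1.0, small_objects = 1.2, dominos = 1.0, key = 0.8,
    nhpt = 1.4, big_objects = 0.8, bottle = 1.0, ball = 0.6,
    1.0
  )
}

#' Simulate one wrist trace of a cyclic manual task
#'
#' The trace is a quiescent lead-in, an active window of cyclic movement,
#' and a quiescent lead-out. Rising impairment `level` lengthens the active
#' window (a fully impaired hand takes twice as long), narrows the
#' acceleration spread, disperses spectral energy away from the cycle
#' frequency into broadband noise, and shrinks the angular-velocity range —
#' the signal directions the capacity features are designed to pick up.
#'
#' @param profile an [impairment_profile()].
#' @param task_class one of the manual task classes (see [task_classes()]).
#' @param duration_hint active-movement duration at `level = 0`, s.
#' @param fs sampling rate, Hz.
#' @param seed integer seed; identical arguments give bit-identical output.
#' @param side which hand performs (`"left"`/`"right"`); with
#'   `side_affected` set, the affected hand carries the full level.
#' @param week week number, applied through `week_trend`.
#' @param lead_s nominal quiescent lead-in/out, s.
#' @return list with `trace` (the wrist [imu_trace()]) and `truth` — a list
#'   holding `active_interval` (half-open 0-based samples), `cycle_freq`
#'   (Hz), `level` and the drawn signal parameters.
#' @export
simulate_manual_task <- function(profile, task_class = "cards",
                                 duration_hint = 6, fs = 100, seed = 1L,
                                 side = "right", week = 1L, lead_s = 2) {
  check_positive(fs, "fs")
  check_positive(duration_hint, "duration_hint")
  lev <- effective_level(profile, week, side)
  placement <- if (side == "left") "wrist_L" else "wrist_R"

  with_local_seed(seed, {
    lead_in <- jit(lead_s, 0.15)
    lead_out <- jit(lead_s, 0.15)
    active <- duration_hint * (1 + lev) * exp(runif(1, -0.15, 0.15))
    f0 <- jit(manual_base_freq(task_class), 0.10)
    amp <- 0.35 * (1 - 0.75 * lev) * exp(runif(1, -0.10, 0.10))
    noise_active <- (0.03 + 0.08 * lev) * exp(runif(1, -0.10, 0.10))
    noise_quiet <- 0.01
    gyro_amp <- 180 * (1 - 0.70 * lev) * exp(runif(1, -0.10, 0.10))
    gyro_noise_active <- 2 + 8 * lev
    phase <- runif(1, 0, 2 * pi)

    n_in <- round(lead_in * fs)
    n_act <- round(active * fs)
    n_out <- round(lead_out * fs)
    n <- n_in + n_act + n_out

    acc <- cbind(rnorm(n, 0, noise_quiet), rnorm(n, 0, noise_quiet),
                 1 + rnorm(n, 0, noise_quiet))
    gyr <- cbind(rnorm(n, 0, 1), rnorm(n, 0, 1), rnorm(n, 0, 1))

    # snap the cycle rate to an integer number of half-cycles over the
    # active window and start at cosine phase: the movement then starts
    # and stops at peak excursion (mid-reach), making the signal time-
    # symmetric about its boundaries — the active window has crisp,
    # well-defined energy edges rather than a fade-in
    active_T <- n_act / fs
    f0 <- max(1L, round(2 * f0 * active_T)) / (2 * active_T)

    ia <- seq.int(n_in + 1L, n_in + n_act)
    tt <- (seq_len(n_act) - 1L) / fs
    # vertical cyclic movement modulates the gravity axis directly, so the
    # magnitude carries the cycle frequency itself (not its double)
    acc[ia, 3L] <- 1 + amp * cos(2 * pi * f0 * tt) +
      rnorm(n_act, 0, noise_active)
    acc[ia, 1L] <- 0.4 * amp * sin(2 * pi * f0 * tt) +
      rnorm(n_act, 0, noise_active)
    acc[ia, 2L] <- rnorm(n_act, 0, noise_active)
    gyr[ia, 1L] <- gyro_amp * cos(2 * pi * f0 * tt + phase) +
      rnorm(n_act, 0, gyro_noise_active)
    gyr[ia, 2L] <- 0.5 * gyro_amp * sin(2 * pi * f0 * tt + phase) +
      rnorm(n_act, 0, gyro_noise_active)
    gyr[ia, 3L] <- rnorm(n_act, 0, gyro_noise_active)

    trace <- imu_trace(acc, gyr, fs, placement = placement)
    truth <- list(
      active_interval = c(start = n_in, end = n_in + n_act),
      cycle_freq = f0, level = lev, amplitude = amp,
      noise_sd = noise_active, gyro_amplitude = gyro_amp,
      active_s = n_act / fs
    )
    list(trace = trace, truth = truth)
  })
}

#' Simulate a walking bout measured at hip and both feet
#'
#' Each heel strike is a 30 ms half-sine impact transient (default 2 g
#' above the 1 g baseline) in the foot's acceleration magnitude; during
#' stance the foot rests near 1 g; during swing the magnitude oscillates.
#' Step/stance timing is fully programmable per foot and recorded as ground
#' truth.
#'
#' @param step_dur_left,step_dur_right step duration per foot
#'   (time between consecutive heel strikes of that foot), s.
#' @param stance_frac stance fraction of the step duration, in (0, 1).
#' @param n_steps number of heel strikes per foot (>= 2).
#' @param fs sampling rate, Hz.
#' @param noise_sd accelerometer noise, g.
#' @param seed integer seed.
#' @param spike_g impact-transient amplitude above baseline, g.
#' @param lead_s quiescent lead-in/out, s.
#' @return list with `traces` (named list `hip`, `foot_L`, `foot_R`) and
#'   `truth`: per-foot `heel_strikes` (0-based samples), `step_durations`
#'   and `stance_durations` (s), and the `active_interval`.
#' @export
simulate_gait <- function(step_dur_left = 1.2, step_dur_right = 1.2,
                          stance_frac = 0.6, n_steps = 10L, fs = 100,
                          noise_sd = 0.02, seed = 1L, spike_g = 2,
                          lead_s = 1.5) {
  check_positive(fs, "fs")
  if (stance_frac <= 0 || stance_frac >= 1) {
    stop("`stance_frac` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (n_steps < 2L) stop("`n_steps` must be >= 2", call. = FALSE)

  with_local_seed(seed, {
    t0 <- lead_s
    strikes_l <- t0 + (seq_len(n_steps) - 1L) * step_dur_left
    strikes_r <- t0 + step_dur_left / 2 + (seq_len(n_steps) - 1L) * step_dur_right
    total <- max(c(strikes_l, strikes_r)) +
      max(step_dur_left, step_dur_right) + lead_s
    n <- round(total * fs)

    foot <- function(strikes, step_dur) {
      acc <- cbind(rnorm(n, 0, noise_sd), rnorm(n, 0, noise_sd),
                   1 + rnorm(n, 0, noise_sd))
      gyr <- cbind(rnorm(n, 0, 2), rnorm(n, 0, 2), rnorm(n, 0, 2))
      hw <- max(1L, as.integer(round(0.015 * fs)))
      half_sine <- sin(pi * seq(0, 1, length.out = 2L * hw + 1L))
      for (ts in strikes) {
        c0 <- round(ts * fs) + 1L
        idx <- (c0 - hw):(c0 + hw)
        ok <- idx >= 1L & idx <= n
        acc[idx[ok], 3L] <- acc[idx[ok], 3L] + spike_g * half_sine[ok]
        # swing: elevated oscillation from lift-off to just before next strike
        sw0 <- round((ts + stance_frac * step_dur) * fs) + 1L
        sw1 <- min(n, round((ts + 0.95 * step_dur) * fs))
        if (sw1 > sw0) {
          k <- sw0:sw1
          ph <- 2 * pi * 3 * (k - sw0) / fs
          acc[k, 1L] <- acc[k, 1L] + 0.5 * sin(ph)
          acc[k, 3L] <- acc[k, 3L] + 0.3 * sin(ph + 1)
          gyr[k, 2L] <- gyr[k, 2L] + 120 * sin(ph / 2)
        }
      }
      imu_trace(acc, gyr, fs, placement = "other")
    }

    tl <- foot(strikes_l, step_dur_left)
    tr <- foot(strikes_r, step_dur_right)
    attr(tl, "placement") <- "foot_L"
    attr(tr, "placement") <- "foot_R"

    # hip: gentle vertical bounce at the combined step rate
    tt <- (seq_len(n) - 1L) / fs
    cadence <- 2 / (step_dur_left / 2 + step_dur_right / 2)
    act <- tt >= t0 & tt <= total - lead_s
    acc_h <- cbind(rnorm(n, 0, noise_sd), rnorm(n, 0, noise_sd),
                   1 + rnorm(n, 0, noise_sd))
    acc_h[act, 3L] <- acc_h[act, 3L] + 0.15 * sin(2 * pi * cadence * tt[act])
    acc_h[act, 1L] <- acc_h[act, 1L] + 0.08 * cos(2 * pi * cadence * tt[act])
    gyr_h <- cbind(rnorm(n, 0, 2), rnorm(n, 0, 2), rnorm(n, 0, 2))
    gyr_h[act, 1L] <- gyr_h[act, 1L] + 40 * sin(2 * pi * cadence / 2 * tt[act])
    hip <- imu_trace(acc_h, gyr_h, fs, placement = "hip")

    truth <- list(
      heel_strikes = list(
        L = as.integer(round(strikes_l * fs)),
        R = as.integer(round(strikes_r * fs))
      ),
      step_durations = list(
        L = rep(step_dur_left, n_steps - 1L),
        R = rep(step_dur_right, n_steps - 1L)
      ),
      stance_durations = list(
        L = rep(stance_frac * step_dur_left, n_steps - 1L),
        R = rep(stance_frac * step_dur_right, n_steps - 1L)
      ),
      active_interval = c(start = round(t0 * fs), end = n)
    )
    list(traces = list(hip = hip, foot_L = tl, foot_R = tr), truth = truth)
  })
}

#' Simulate wheelchair propulsion measured at hip and both wrists
#'
#' Trace layout is straight driving (`n_cycles` push cycles), a turn of
#' `turn_dur` seconds with distinct (low-activity) signal statistics, and
#' straight driving back (`n_cycles` cycles). Every push cycle produces one
#' dominant acceleration peak per wrist during the forward push and a
#' smaller peak during the backward release; the left wrist lags the right
#' by `lag_frac` of the cycle duration.
#'
#' @param cycle_dur push-cycle duration, s.
#' @param lag_frac left-wrist lag as a fraction of the cycle, in
#'   `[0, 0.5]`.
#' @param n_cycles push cycles per straight block (>= 2).
#' @param turn_dur duration of the turning block, s.
#' @param fs sampling rate, Hz.
#' @param noise_sd accelerometer noise, g.
#' @param seed integer seed.
#' @return list with `traces` (`hip`, `wrist_L`, `wrist_R`) and `truth`:
#'   `push_cycle_lag`, per-wrist push-peak sample indices, and
#'   `segment_breakpoints` — 0-based sample indices of the
#'   straight/turn/straight boundaries `c(0, turn_start, turn_end, n)`.
#' @export
simulate_wheelchair <- function(cycle_dur = 1.0, lag_frac = 0.1,
                                n_cycles = 6L, turn_dur = 3, fs = 100,
                                noise_sd = 0.01, seed = 1L) {
  check_positive(fs, "fs")
  if (lag_frac < 0 || lag_frac > 0.5) {
    stop("`lag_frac` must lie in [0, 0.5]", call. = FALSE)
  }
  if (n_cycles < 2L) stop("`n_cycles` must be >= 2", call. = FALSE)

  with_local_seed(seed, {
    block <- n_cycles * cycle_dur
    turn_start <- block
    turn_end <- block + turn_dur
    total <- turn_end + block
    n <- round(total * fs)
    tt <- (seq_len(n) - 1L) / fs

    bump <- function(centres, width, amp) {
      y <- numeric(n)
      for (tc in centres) {
        y <- y + amp * exp(-0.5 * ((tt - tc) / width)^2)
      }
      y
    }
    push_r <- c(
      (seq_len(n_cycles) - 1L) * cycle_dur + 0.25 * cycle_dur,
      turn_end + (seq_len(n_cycles) - 1L) * cycle_dur + 0.25 * cycle_dur
    )
    push_l <- push_r + lag_frac * cycle_dur
    # the release bump (and its lag) must finish inside its own cycle so
    # that propulsion activity ends exactly at the nominal turn boundary
    release_lag <- min(0.30, 1.5 * lag_frac + 0.03)
    rel_r <- push_r + 0.55 * cycle_dur
    rel_l <- push_r + 0.55 * cycle_dur + release_lag * cycle_dur

    wrist <- function(push, rel, placement) {
      acc <- cbind(rnorm(n, 0, noise_sd), rnorm(n, 0, noise_sd),
                   1 + rnorm(n, 0, noise_sd))
      acc[, 3L] <- acc[, 3L] + bump(push, 0.06, 1.2) + bump(rel, 0.06, 0.5)
      gyr <- cbind(rnorm(n, 0, 2), rnorm(n, 0, 2), rnorm(n, 0, 2))
      gyr[, 2L] <- gyr[, 2L] + bump(push, 0.10, 150)
      imu_trace(acc, gyr, fs, placement = placement)
    }
    wl <- wrist(push_l, rel_l, "wrist_L")
    wr <- wrist(push_r, rel_r, "wrist_R")

    # hip: forward surge each push; yaw rotation during the turn
    acc_h <- cbind(rnorm(n, 0, noise_sd), rnorm(n, 0, noise_sd),
                   1 + rnorm(n, 0, noise_sd))
    acc_h[, 1L] <- acc_h[, 1L] +
      bump((push_l + push_r) / 2, 0.12, 0.3)
    gyr_h <- cbind(rnorm(n, 0, 2), rnorm(n, 0, 2), rnorm(n, 0, 2))
    in_turn <- tt >= turn_start & tt < turn_end
    gyr_h[in_turn, 3L] <- gyr_h[in_turn, 3L] +
      60 * sin(pi * (tt[in_turn] - turn_start) / turn_dur)
    hip <- imu_trace(acc_h, gyr_h, fs, placement = "hip")

    truth <- list(
      push_cycle_lag = lag_frac,
      cycle_dur = cycle_dur,
      push_peaks = list(
        L = as.integer(round(push_l * fs)),
        R = as.integer(round(push_r * fs))
      ),
      segment_breakpoints = as.integer(round(
        c(0, turn_start, turn_end, total) * fs
      )),
      active_interval = c(start = 0L, end = n)
    )
    list(traces = list(hip = hip, wrist_L = wl, wrist_R = wr), truth = truth)
  })
}

#' Simulate the labeling-sensor trace
#'
#' The experiment leader marks each task start with one fast rotation and
#' each task end with a fast double rotation of a hand-held sensor,
#' producing sharp bursts on its x-axis gyroscope over a low-noise
#' background.
#'
#' @param task_intervals list of `c(start_s, end_s)` task intervals,
#'   sorted and non-overlapping (with at least ~1.5 s between tasks so that
#'   the double burst of one end cannot merge with the next start).
#' @param fs sampling rate, Hz.
#' @param seed integer seed.
#' @param total_dur_s trace duration; default extends 2 s past the last end.
#' @param burst_dps burst amplitude, deg/s.
#' @return a `labeler` [imu_trace()].
#' @export
simulate_labeling_trace <- function(task_intervals, fs = 100, seed = 1L,
                                    total_dur_s = NULL, burst_dps = 500) {
  check_positive(fs, "fs")
  if (length(task_intervals) > 0L) {
    m <- do.call(rbind, task_intervals)
    if (any(m[, 2L] <= m[, 1L])) {
      stop("each interval must satisfy start < end", call. = FALSE)
    }
    if (nrow(m) > 1L) {
      o <- order(m[, 1L])
      if (any(m[o, 1L][-1L] < m[o, 2L][-nrow(m)])) {
        stop("task intervals must be sorted and non-overlapping",
          call. = FALSE
        )
      }
      if (any(diff(m[o, 1L]) <= 0)) {
        stop("task intervals must be sorted and non-overlapping",
          call. = FALSE
        )
      }
    }
  }
  if (is.null(total_dur_s)) {
    total_dur_s <- if (length(task_intervals) == 0L) {
      10
    } else {
      max(vapply(task_intervals, `[`, numeric(1), 2L)) + 2
    }
  }

  with_local_seed(seed, {
    n <- round(total_dur_s * fs)
    gx <- rnorm(n, 0, 3)
    burst_len <- round(0.12 * fs)
    half_sine <- sin(pi * seq(0, 1, length.out = burst_len))
    add_burst <- function(gx, t_s) {
      i0 <- round(t_s * fs) + 1L
      idx <- i0:(i0 + burst_len - 1L)
      ok <- idx >= 1L & idx <= n
      gx[idx[ok]] <- gx[idx[ok]] + burst_dps * half_sine[ok]
      gx
    }
    for (iv in task_intervals) {
      gx <- add_burst(gx, iv[1L])              # single burst: start
      gx <- add_burst(gx, iv[2L])              # double burst: end
      gx <- add_burst(gx, iv[2L] + 0.35)
    }
    acc <- cbind(rnorm(n, 0, 0.01), rnorm(n, 0, 0.01), 1 + rnorm(n, 0, 0.01))
    gyr <- cbind(gx, rnorm(n, 0, 3), rnorm(n, 0, 3))
    imu_trace(acc, gyr, fs, placement = "labeler")
  })
}
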