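#' Magnitude of a 3-axis IMU channel
#'
#' Per-sample Euclidean norm of the acceleration or angular-velocity
#' 3-vector. Working on magnitudes rather than individual axes makes every
#' downstream feature invariant to the sensor's orientation, which is the
#' basis for robustness against sensor displacement between and within
#' sessions.
#'
#' @param trace an [imu_trace()].
#' @param channel `"accel"` (result in g) or `"gyro"` (result in deg/s).
#' @return numeric vector, one value per sample, all `>= 0`.
#' @export
magnitude <- function(trace, channel = c("accel", "gyro")) {
  stopifnot(is_imu_trace(trace))
  channel <- match.arg(channel)
  m <- if (channel == "accel") accel_matrix(trace) else gyro_matrix(trace)
  sqrt(rowSums(m^2))
}

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth low-pass applied forward and backward
#' (zero phase, so detected event times are not shifted), with unit DC gain.
#' The default 45 Hz cutoff at a 100 Hz sampling rate is close to Nyquist
#' and acts mainly as a noise guard.
#'
#' @param x numeric series.
#' @param fs sampling rate, Hz.
#' @param cutoff cutoff frequency, Hz; must satisfy `0 < cutoff < fs/2`.
#' @param order filter order (of the underlying one-pass Butterworth).
#' @return filtered series, same length as `x`.
#' @export
lowpass <- function(x, fs, cutoff = 45, order = 4L) {
  check_positive(fs, "fs")
  check_positive(cutoff, "cutoff")
  if (cutoff >= fs / 2) {
    stop(sprintf(
      "`cutoff` (%g Hz) must be below the Nyquist frequency (%g Hz)",
      cutoff, fs / 2
    ), call. = FALSE)
  }
  n <- length(x)
  if (n < 3L * (order + 1L)) {
    # too short for stable edge handling; pass through unchanged
    return(x)
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # odd (point-symmetric) reflection padding long enough for the filter's
  # start-up transient to decay below numerical noise, so edges are clean
  # and a constant series passes through exactly
  poles <- Mod(polyroot(rev(bf$a)))
  decay <- max(poles[poles < 1], 0.1)
  p <- min(n - 1L, max(50L, ceiling(log(1e-14) / log(decay))))
  xp <- c(2 * x[1L] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(p + 1L):(p + n)]
}

#' Low-pass filter all six channels of a trace
#'
#' Filters each acceleration and angular-velocity axis with [lowpass()]
#' before any magnitude is taken, so magnitudes of the filtered trace remain
#' non-negative.
#'
#' @inheritParams magnitude
#' @inheritParams lowpass
#' @return a filtered `imu_trace`.
#' @export
lowpass_trace <- function(trace, cutoff = 45, order = 4L) {
  stopifnot(is_imu_trace(trace))
  fs <- trace_fs(trace)
  out <- trace
  for (col in c("ax_g", "ay_g", "az_g", "gx_dps", "gy_dps", "gz_dps")) {
    out[[col]] <- lowpass(trace[[col]], fs, cutoff = cutoff, order = order)
  }
  out
}

# Detect short supra-threshold rotation bursts on the labeling sensor's
# x-gyroscope. A robust noise gate (`mad_mult` median absolute deviations
# of |gx| above its median) decides whether any bursts are present at all;
# actual peaks are then thresholded relative to the strongest burst, so
# rare noise excursions just past the MAD gate in a long recording cannot
# masquerade as label events. Bursts closer than `burst_gap_s` are the
# same burst.
detect_bursts <- function(gx, fs, mad_mult = 6, burst_gap_s = 0.2) {
  a <- abs(gx)
  gate <- median(a) + mad_mult * mad(a)
  if (max(a) < 2 * gate) return(integer(0)) # no credible burst anywhere
  thr <- max(gate, 0.3 * max(a))
  find_peaks(a, threshold = thr, min_gap = as.integer(round(burst_gap_s * fs)))
}

#' Detect task boundaries from the labeling sensor
#'
#' During recording the experiment leader marks the start of every task with
#' a fast single rotation of a hand-held labeling sensor and the end with a
#' fast double rotation. Both evoke sharp bursts on the sensor's x-axis
#' gyroscope. This detector finds supra-threshold bursts (threshold: a
#' configurable multiple of the median absolute deviation of `|gx|`), groups
#' bursts closer than `group_window_s` into one event, classifies events with
#' one burst as starts and two bursts as ends, and pairs each start with the
#' following end.
#'
#' @param trace an [imu_trace()] with placement `"labeler"`.
#' @param mad_mult burst threshold as a multiple of the MAD of `|gx|`.
#' @param group_window_s bursts within this window form one event (s).
#' @param burst_gap_s minimum spacing between distinct bursts (s).
#' @return tibble with columns `start` and `end` (half-open, 0-based sample
#'   indices) and `start_s`, `end_s` (seconds), one row per task, sorted and
#'   non-overlapping. Zero rows if no bursts are found.
#' @export
detect_task_boundaries <- function(trace, mad_mult = 6,
                                   group_window_s = 1.0,
                                   burst_gap_s = 0.2) {
  stopifnot(is_imu_trace(trace))
  if (trace_placement(trace) != "labeler") {
    stop("`trace` must come from the labeling sensor (placement 'labeler')",
      call. = FALSE
    )
  }
  fs <- trace_fs(trace)
  peaks <- detect_bursts(trace$gx_dps, fs,
    mad_mult = mad_mult,
    burst_gap_s = burst_gap_s
  )
  empty <- tibble::tibble(
    start = integer(0), end = integer(0),
    start_s = numeric(0), end_s = numeric(0)
  )
  if (length(peaks) == 0L) return(empty)

  # group bursts within the window into events
  gap <- c(Inf, diff(peaks)) / fs
  event_id <- cumsum(gap > group_window_s)
  events <- tibble::tibble(peak = peaks, event = event_id) |>
    dplyr::group_by(.data$event) |>
    dplyr::summarise(
      t = .data$peak[1L],
      n_bursts = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(kind = ifelse(.data$n_bursts >= 2L, "end", "start"))

  kinds <- events$kind
  expected <- rep(c("start", "end"), length.out = length(kinds))
  if (length(kinds) %% 2L != 0L || !all(kinds == expected)) {
    orphans <- events$t[kinds != rep(c("start", "end"),
      length.out = length(kinds)
    )]
    if (length(orphans) == 0L) orphans <- tail(events$t, 1L)
    stop(sprintf(
      "unmatched start/end label events at t = %s s",
      paste(sprintf("%.2f", orphans / fs), collapse = ", ")
    ), call. = FALSE)
  }

  starts <- events$t[kinds == "start"] - 1L # 0-based
  ends <- events$t[kinds == "end"] - 1L
  tibble::tibble(
    start = as.integer(starts), end = as.integer(ends),
    start_s = starts / fs, end_s = ends / fs
  )
}

#' Detect the synchronization clap
#'
#' Recordings open and close with a calibration pose ending in a hand clap,
#' which evokes a single dominant spike in the wrist acceleration magnitude
#' and is used to align sensor data with video. Returns the sample index of
#' the largest above-threshold transient.
#'
#' @param accel_mag acceleration-magnitude series, g.
#' @param fs sampling rate, Hz.
#' @param threshold minimum magnitude (g) for a sample to count as a clap.
#' @return 0-based sample index of the clap peak.
#' @export
detect_sync_clap <- function(accel_mag, fs, threshold = 2.5) {
  if (length(accel_mag) == 0L) stop("`accel_mag` is empty", call. = FALSE)
  if (max(accel_mag) <= threshold) {
    stop(sprintf(
      "no clap found: no sample exceeds %.2f g", threshold
    ), call. = FALSE)
  }
  as.integer(which.max(accel_mag) - 1L)
}
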