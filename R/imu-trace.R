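#' Build an IMU trace
#'
#' An IMU trace is a tibble with one row per sample and columns `time_s`,
#' `ax_g`, `ay_g`, `az_g` (3-axis acceleration in g) and `gx_dps`, `gy_dps`,
#' `gz_dps` (3-axis angular velocity in deg/s), carrying the sample rate and
#' the body placement of the sensor as attributes. All downstream analysis
#' works on the Euclidean magnitude of the two 3-vectors, so a trace is valid
#' under any fixed rotation of its axes.
#'
#' @param accel numeric matrix (n x 3) of accelerations, g.
#' @param gyro numeric matrix (n x 3) of angular velocities, deg/s.
#' @param fs sampling rate, Hz.
#' @param placement one of `placement_levels()`: `"wrist_L"`, `"wrist_R"`,
#'   `"hip"`, `"foot_L"`, `"foot_R"`, `"upper_leg_L"`, `"upper_leg_R"`,
#'   `"trunk"`, `"labeler"`, `"other"`.
#' @return a tibble of class `imu_trace` with attributes `fs` and
#'   `placement`.
#' @examples
#' tr <- imu_trace(matrix(c(0, 0, 1), 5, 3, byrow = TRUE),
#'                 matrix(0, 5, 3), fs = 100, placement = "wrist_R")
#' magnitude(tr, "accel")
#' @export
imu_trace <- function(accel, gyro, fs, placement = "other") {
  accel <- as.matrix(accel)
  gyro <- as.matrix(gyro)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  if (ncol(accel) != 3L || ncol(gyro) != 3L) {
    stop("`accel` and `gyro` must have 3 columns (x, y, z)", call. = FALSE)
  }
  if (nrow(accel) != nrow(gyro) || nrow(accel) == 0L) {
    stop("`accel` and `gyro` must have equal, non-zero length", call. = FALSE)
  }
  if (!all(is.finite(accel)) || !all(is.finite(gyro))) {
    stop("IMU samples must all be finite", call. = FALSE)
  }
  placement <- match.arg(placement, placement_levels())
  n <- nrow(accel)
  out <- tibble::tibble(
    time_s = (seq_len(n) - 1L) / fs,
    ax_g = accel[, 1L], ay_g = accel[, 2L], az_g = accel[, 3L],
    gx_dps = gyro[, 1L], gy_dps = gyro[, 2L], gz_dps = gyro[, 3L]
  )
  new_imu_trace(out, fs = fs, placement = placement)
}

new_imu_trace <- function(df, fs, placement) {
  structure(df,
    fs = fs, placement = placement,
    class = c("imu_trace", class(tibble::tibble()))
  )
}

#' @rdname imu_trace
#' @export
placement_levels <- function() {
  c(
    "wrist_L", "wrist_R", "hip", "foot_L", "foot_R",
    "upper_leg_L", "upper_leg_R", "trunk", "labeler", "other"
  )
}

#' @rdname imu_trace
#' @param x an object.
#' @export
is_imu_trace <- function(x) inherits(x, "imu_trace")

#' Sample rate and placement accessors
#'
#' @param trace an [imu_trace()].
#' @return `trace_fs()` the sampling rate in Hz; `trace_placement()` the
#'   placement string; `trace_length()` the number of samples.
#' @export
trace_fs <- function(trace) attr(trace, "fs")

#' @rdname trace_fs
#' @export
trace_placement <- function(trace) attr(trace, "placement")

#' @rdname trace_fs
#' @export
trace_length <- function(trace) nrow(trace)

accel_matrix <- function(trace) {
  cbind(trace$ax_g, trace$ay_g, trace$az_g)
}

gyro_matrix <- function(trace) {
  cbind(trace$gx_dps, trace$gy_dps, trace$gz_dps)
}

#' Extract a half-open sample window of a trace
#'
#' Intervals are half-open `[start, end)` in 0-based samples throughout the
#' package, matching how task segments are stored.
#'
#' @param trace an [imu_trace()].
#' @param start,end 0-based sample indices, `start < end <= trace_length`.
#' @return an `imu_trace` covering samples `start, ..., end - 1`, with
#'   `time_s` restarted at 0.
#' @export
trace_window <- function(trace, start, end) {
  stopifnot(is_imu_trace(trace))
  n <- trace_length(trace)
  if (start < 0 || end > n || start >= end) {
    stop(sprintf(
      "invalid window [%d, %d) for trace of length %d", start, end, n
    ), call. = FALSE)
  }
  idx <- seq.int(start + 1L, end)
  out <- trace[idx, , drop = FALSE]
  out$time_s <- out$time_s - out$time_s[1L]
  new_imu_trace(out, fs = trace_fs(trace), placement = trace_placement(trace))
}

#' @export
print.imu_trace <- function(x, ...) {
  cat(sprintf(
    "<imu_trace> placement=%s fs=%g Hz n=%d (%.2f s)\n",
    trace_placement(x), trace_fs(x), nrow(x), nrow(x) / trace_fs(x)
  ))
  NextMethod()
}
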