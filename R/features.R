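#' Movement onset, offset and task completion time (TIME)
#'
#' The standard deviation of the acceleration magnitude is computed over a
#' sliding window (default 0.5 s, advancing by `window - overlap` = 0.01 s)
#' and compared against a threshold to decide when the hand (or body) is
#' moving. The reported onset and offset are the centres of the first and
#' last supra-threshold windows: with the default threshold — the variance
#' midpoint between the quiescent floor (10th percentile of window stds) and
#' the active level (90th percentile) — a window first crosses threshold
#' when it is about half filled with movement, so its centre sits at the
#' true movement edge regardless of movement amplitude. TIME is
#' `offset - onset` in seconds.
#'
#' If no window exceeds threshold, or the active level is indistinguishable
#' from the noise floor (below `min_ratio` times the quiescent std), the
#' result is flagged `moved = FALSE` with `time_s = NA` — distinct from a
#' zero-length movement.
#'
#' @param accel_mag acceleration-magnitude series, g.
#' @param fs sampling rate, Hz.
#' @param window sliding-window length, s.
#' @param overlap overlap between consecutive windows, s (step =
#'   `window - overlap`).
#' @param threshold absolute std threshold in g; `NULL` (default) uses the
#'   adaptive variance-midpoint rule described above.
#' @param min_ratio minimum active/quiescent std ratio for the trace to
#'   count as containing movement at all.
#' @param smooth extra symmetric smoothing of the window-power profile, s;
#'   `NULL` (default) adapts it to one cycle of the series' dominant
#'   frequency, which cancels the power ripple of cyclic movement.
#' @return a one-row tibble: `onset`, `offset` (0-based samples), `onset_s`,
#'   `offset_s`, `time_s`, `moved`.
#' @export
movement_interval <- function(accel_mag, fs, window = 0.5, overlap = 0.49,
                              threshold = NULL, min_ratio = 3,
                              smooth = NULL) {
  check_positive(fs, "fs")
  check_positive(window, "window")
  if (overlap < 0 || overlap >= window) {
    stop("`overlap` must lie in [0, window)", call. = FALSE)
  }
  k <- as.integer(round(window * fs))
  step <- max(1L, as.integer(round((window - overlap) * fs)))
  if (length(accel_mag) <= k) {
    stop("series is shorter than one analysis window", call. = FALSE)
  }
  # per-window movement power about the global quiescent baseline (the
  # magnitude median, ~1 g): a window sliding into the active region gains
  # power linearly in its overlap fraction, so the rise is linear and the
  # midpoint threshold crosses exactly when the window is half filled with
  # movement, making the window-centre onset/offset estimate unbiased.
  # (Subtracting the per-window mean instead would discard the energy of
  # movement cycles slower than the window and bias the boundaries inward.)
  a2 <- (accel_mag - median(accel_mag))^2
  ca <- cumsum(c(0, a2))
  i <- seq_len(length(a2) - k + 1L)
  vars_all <- (ca[i + k] - ca[i]) / k
  if (is.null(smooth)) {
    # match the smoothing span to the power-ripple period of the movement
    # cycle (half the cycle period), which averages the ripple away;
    # parabolic interpolation of the spectral peak gives the sub-bin
    # frequency precision the matching needs on short series
    smooth <- max(0.4, min(0.8, 1 / (2 * .peak_frequency(accel_mag, fs))))
  }
  # symmetric smoothing of the power profile: suppresses both the cycle
  # ripple and stochastic fluctuation of the plateau power (which
  # otherwise jitter the threshold-crossing time) without biasing the
  # linear rise's midpoint. Applied twice (triangular kernel): a single
  # box average nulls the ripple only at its exact period, while the
  # squared response also tolerates the estimation error in the ripple
  # period itself.
  vars_all <- moving_average(vars_all, as.integer(round(smooth * fs)))
  starts <- seq.int(1L, length(vars_all), by = step)
  vars <- vars_all[starts]

  no_movement <- tibble::tibble(
    onset = NA_integer_, offset = NA_integer_,
    onset_s = NA_real_, offset_s = NA_real_,
    time_s = NA_real_, moved = FALSE
  )

  quiet <- quantile(vars, 0.10, names = FALSE)
  active <- quantile(vars, 0.90, names = FALSE)
  if (is.null(threshold)) {
    if (active < min_ratio^2 * max(quiet, .Machine$double.eps)) {
      return(no_movement)
    }
    # refine the two levels as class means (stabler than percentiles):
    # provisional midpoint, then midpoint of the mean quiescent and mean
    # active window power. Each class is eroded by the ramp half-width
    # first, so the transition samples (mid-way between the two levels by
    # construction) do not drag the level estimates toward each other —
    # that dilution biases boundaries outward on short bursts.
    ramp_half <- (k + as.integer(round(smooth * fs))) %/% 2L + 2L
    erode <- function(mask, r) {
      runs <- rle(mask)
      out <- rep(runs$values, runs$lengths)
      pos <- 1L
      for (j in seq_along(runs$lengths)) {
        len <- runs$lengths[j]
        if (runs$values[j]) {
          if (len > 2L * r) {
            out[c(pos:(pos + r - 1L), (pos + len - r):(pos + len - 1L))] <-
              FALSE
          } else {
            out[pos:(pos + len - 1L)] <- FALSE
          }
        }
        pos <- pos + len
      }
      out
    }
    thr_var <- (quiet + active) / 2
    for (it in 1:2) {
      hi <- vars > thr_var
      if (!any(hi) || all(hi)) break
      hi_core <- erode(hi, ramp_half)
      lo_core <- erode(!hi, ramp_half)
      hi_lvl <- if (any(hi_core)) mean(vars[hi_core]) else mean(vars[hi])
      lo_lvl <- if (any(lo_core)) mean(vars[lo_core]) else mean(vars[!hi])
      thr_var <- (lo_lvl + hi_lvl) / 2
    }
  } else {
    thr_var <- threshold^2
  }
  above <- which(vars > thr_var)
  if (length(above) == 0L) return(no_movement)

  # sub-step refinement: linear interpolation of the threshold crossing
  centre <- function(i) starts[i] - 1L + (k - 1L) / 2 # 0-based window centre
  i1 <- above[1L]
  onset <- centre(i1)
  if (i1 > 1L && vars[i1] > vars[i1 - 1L]) {
    onset <- onset - step * (vars[i1] - thr_var) / (vars[i1] - vars[i1 - 1L])
  }
  i2 <- above[length(above)]
  offset <- centre(i2)
  if (i2 < length(vars) && vars[i2] > vars[i2 + 1L]) {
    offset <- offset + step * (vars[i2] - thr_var) / (vars[i2] - vars[i2 + 1L])
  }
  tibble::tibble(
    onset = as.integer(round(onset)),
    offset = as.integer(round(offset)),
    onset_s = onset / fs, offset_s = offset / fs,
    time_s = (offset - onset) / fs, moved = TRUE
  )
}

#' Movement intensity (MI)
#'
#' Mean over samples of the instantaneous acceleration magnitude
#' `sqrt(ax^2 + ay^2 + az^2)`, in g — the average intensity of movement over
#' the task, independent of sensor orientation.
#'
#' @param accel n x 3 acceleration matrix (g), or an [imu_trace()].
#' @return MI in g.
#' @export
movement_intensity <- function(accel) {
  mean(.accel_mag_of(accel))
}

#' Movement intensity variation (MIV)
#'
#' Root-mean-square deviation of the instantaneous acceleration magnitude
#' about its task mean (population divisor): the spread of the acceleration-
#' magnitude histogram, a measure of movement variability.
#'
#' @inheritParams movement_intensity
#' @return MIV in g.
#' @export
movement_intensity_variation <- function(accel) {
  m <- .accel_mag_of(accel)
  sqrt(mean((m - mean(m))^2))
}

.accel_mag_of <- function(accel) {
  if (is_imu_trace(accel)) return(magnitude(accel, "accel"))
  accel <- as.matrix(accel)
  if (nrow(accel) == 0L) stop("empty acceleration input", call. = FALSE)
  if (ncol(accel) == 3L) return(sqrt(rowSums(accel^2)))
  if (ncol(accel) == 1L) return(as.numeric(accel))
  stop("acceleration input must be n x 3 (axes) or a magnitude vector",
    call. = FALSE
  )
}

# Spectral-peak frequency refined by parabolic interpolation of the log
# energy across the peak's neighbour bins (sub-bin precision; plain
# dominant_frequency() keeps the documented bin-resolution contract).
.peak_frequency <- function(x, fs) {
  spec <- energy_spectrum(x, fs)
  i <- which.max(spec$energy)
  if (i <= 1L || i >= nrow(spec)) return(spec$freq_hz[i])
  e <- log(pmax(spec$energy[(i - 1L):(i + 1L)], 1e-300))
  denom <- e[1L] - 2 * e[2L] + e[3L]
  delta <- if (abs(denom) < 1e-12) 0 else 0.5 * (e[1L] - e[3L]) / denom
  delta <- max(-0.5, min(0.5, delta))
  spec$freq_hz[i] + delta * fs / length(x)
}

# One-sided energy spectrum (DC removed, positive-frequency bins only).
# Energy = squared modulus of the FFT coefficient.
energy_spectrum <- function(x, fs) {
  n <- length(x)
  if (n < 2L) stop("series must have at least 2 samples", call. = FALSE)
  X <- fft(x - mean(x))
  n_pos <- floor(n / 2)
  idx <- seq.int(2L, n_pos + 1L) # positive frequencies, DC excluded
  tibble::tibble(
    freq_hz = (idx - 1L) * fs / n,
    energy = Mod(X[idx])^2
  )
}

#' Dominant frequency (DF)
#'
#' Frequency of the highest-energy bin of the Fourier-transformed
#' magnitude series, after removal of the mean (the DC component carries the
#' gravity offset, not movement). Ties are broken toward the lowest
#' frequency. Reflects the rate at which the movement was performed.
#'
#' @param x magnitude series.
#' @param fs sampling rate, Hz.
#' @return DF in Hz (resolution `fs / length(x)`).
#' @export
dominant_frequency <- function(x, fs) {
  spec <- energy_spectrum(x, fs)
  spec$freq_hz[which.max(spec$energy)] # which.max takes the first (lowest f)
}

#' Spectral smoothness of movement (SM)
#'
#' Fraction of the (DC-removed, positive-frequency) spectral energy that
#' falls within a 0.2 Hz band centred on the dominant frequency
#' (`DF - 0.1` to `DF + 0.1` Hz, boundary bins inclusive). A periodic,
#' controlled movement concentrates its energy at the movement frequency and
#' scores near 1; fragmented or irregular movement disperses energy and
#' scores near 0. A fixed 0.2 Hz band (rather than a fixed number of bins)
#' keeps the measure comparable across task durations, whose FFT resolutions
#' differ.
#'
#' A bin belongs to the band when its own frequency interval (bin centre
#' plus/minus half the spectral resolution) overlaps the band, so a tone
#' falling between two bin centres keeps both of its split-energy bins.
#' For series shorter than `bandwidth_hz` resolution (duration < 5 s at the
#' 0.2 Hz default) the band collapses to the single DF bin; the result then
#' carries attribute `band_limited = TRUE`.
#'
#' @inheritParams dominant_frequency
#' @param bandwidth_hz width of the band around DF, Hz.
#' @return SM, dimensionless in `[0, 1]`.
#' @export
smoothness <- function(x, fs, bandwidth_hz = 0.2) {
  spec <- energy_spectrum(x, fs)
  df <- spec$freq_hz[which.max(spec$energy)]
  resolution <- fs / length(x)
  band_limited <- resolution > bandwidth_hz
  half <- bandwidth_hz / 2
  in_band <- if (band_limited) {
    spec$freq_hz == df
  } else {
    abs(spec$freq_hz - df) <= half + resolution / 2 + 1e-9
  }
  total <- sum(spec$energy)
  sm <- if (total > 0) sum(spec$energy[in_band]) / total else 0
  structure(min(max(sm, 0), 1), band_limited = band_limited)
}

#' Average rotation energy (ARE)
#'
#' Mean over samples of the squared angular-velocity magnitude
#' `gx^2 + gy^2 + gz^2`, in (deg/s)^2 — the average rotational energy of the
#' movement over the whole task.
#'
#' @param gyro n x 3 angular-velocity matrix (deg/s), or an [imu_trace()].
#' @return ARE in (deg/s)^2.
#' @export
average_rotation_energy <- function(gyro) {
  mean(.gyro_mag_of(gyro)^2)
}

#' Range of angular velocity (RANG)
#'
#' Maximum minus minimum of the angular-velocity magnitude series, in deg/s;
#' indicates how fast movements were performed.
#'
#' @inheritParams average_rotation_energy
#' @return RANG in deg/s, `>= 0`.
#' @export
range_angular_velocity <- function(gyro) {
  m <- .gyro_mag_of(gyro)
  max(m) - min(m)
}

.gyro_mag_of <- function(gyro) {
  if (is_imu_trace(gyro)) return(magnitude(gyro, "gyro"))
  gyro <- as.matrix(gyro)
  if (nrow(gyro) == 0L) stop("empty gyroscope input", call. = FALSE)
  if (ncol(gyro) == 3L) return(sqrt(rowSums(gyro^2)))
  if (ncol(gyro) == 1L) return(as.numeric(gyro))
  stop("gyroscope input must be n x 3 (axes) or a magnitude vector",
    call. = FALSE
  )
}
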