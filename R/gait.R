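#' Detect heel strikes and lift-offs from a foot sensor
#'
#' Each heel strike produces a sharp impact transient in the foot's
#' acceleration magnitude. During stance the foot rests on the ground and
#' the magnitude sits close to 1 g (gravity); when the foot lifts off and
#' swings, the magnitude departs the 1 g plateau again. Strikes are detected
#' as supra-threshold peaks with a refractory spacing; the lift-off between
#' two strikes is the first sample (after a short post-impact blanking
#' interval) whose smoothed deviation from 1 g exceeds `swing_threshold`.
#'
#' @param accel_mag foot acceleration-magnitude series, g.
#' @param fs sampling rate, Hz.
#' @param strike_threshold minimum peak magnitude for a heel strike, g.
#' @param refractory_s minimum spacing between strikes, s.
#' @param swing_threshold deviation from the 1 g stance plateau that marks
#'   lift-off, g.
#' @param blank_s post-strike blanking before lift-off search, s.
#' @return a `gait_events` list: `strikes` (0-based sample indices),
#'   `lift_offs` (0-based; `lift_offs[k]` lies between `strikes[k]` and
#'   `strikes[k + 1]`, `NA` where no lift-off was found), and `fs`. No
#'   events is an empty result, not an error.
#' @export
detect_heel_strikes <- function(accel_mag, fs, strike_threshold = 1.8,
                                refractory_s = 0.4, swing_threshold = 0.15,
                                blank_s = 0.1) {
  if (length(accel_mag) == 0L) stop("`accel_mag` is empty", call. = FALSE)
  check_positive(fs, "fs")
  strikes <- find_peaks(accel_mag,
    threshold = strike_threshold,
    min_gap = as.integer(round(refractory_s * fs))
  )
  if (length(strikes) < 2L) {
    return(gait_events(strikes - 1L, integer(0), fs))
  }
  dev <- moving_average(abs(accel_mag - 1), 5L)
  blank <- as.integer(round(blank_s * fs))
  lift_offs <- vapply(seq_len(length(strikes) - 1L), function(k) {
    lo <- strikes[k] + blank
    hi <- strikes[k + 1L] - blank
    if (lo >= hi) return(NA_integer_)
    w <- which(dev[lo:hi] > swing_threshold)
    if (length(w) == 0L) NA_integer_ else lo + w[1L] - 1L
  }, integer(1))
  gait_events(strikes - 1L, lift_offs - 1L, fs)
}

#' @rdname detect_heel_strikes
#' @param strikes,lift_offs 0-based sample indices.
#' @export
gait_events <- function(strikes, lift_offs, fs) {
  strikes <- as.integer(strikes)
  lift_offs <- as.integer(lift_offs)
  if (is.unsorted(strikes, strictly = TRUE) && length(strikes) > 1L) {
    stop("heel strikes must be strictly increasing", call. = FALSE)
  }
  structure(
    list(strikes = strikes, lift_offs = lift_offs, fs = fs),
    class = "gait_events"
  )
}

#' Step and stance durations with left/right symmetry ratios
#'
#' Step duration is the time between two consecutive heel strikes of the
#' same foot; stance duration is the time from a heel strike to the
#' following lift-off of that foot. Averages pool the per-cycle durations of
#' both feet; the symmetry ratios are right/left of the per-foot mean
#' durations (1 = symmetric gait).
#'
#' @param events_left,events_right `gait_events` of the left and right foot
#'   (see [detect_heel_strikes()]).
#' @param fs sampling rate, Hz.
#' @return one-row tibble: `T_step_avg` (s), `T_step_ratio`,
#'   `T_stance_avg` (s), `T_stance_ratio`.
#' @export
gait_durations <- function(events_left, events_right, fs) {
  durs <- function(ev, foot) {
    if (length(ev$strikes) < 2L) {
      stop(sprintf(
        "need at least 2 heel strikes on the %s foot (got %d)",
        foot, length(ev$strikes)
      ), call. = FALSE)
    }
    step <- diff(ev$strikes) / fs
    k <- seq_len(min(length(ev$lift_offs), length(ev$strikes) - 1L))
    stance <- (ev$lift_offs[k] - ev$strikes[k]) / fs
    stance <- stance[is.finite(stance) & stance > 0]
    if (length(stance) == 0L) {
      stop(sprintf("no stance phases found on the %s foot", foot),
        call. = FALSE
      )
    }
    list(step = step, stance = stance)
  }
  l <- durs(events_left, "left")
  r <- durs(events_right, "right")
  tibble::tibble(
    T_step_avg = mean(c(l$step, r$step)),
    T_step_ratio = mean(r$step) / mean(l$step),
    T_stance_avg = mean(c(l$stance, r$stance)),
    T_stance_ratio = mean(r$stance) / mean(l$stance)
  )
}
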