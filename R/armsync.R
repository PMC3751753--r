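#' Bilateral arm synchrony during wheelchair propulsion
#'
#' Each push cycle has a forward pushing phase and a backward release phase,
#' both visible as acceleration peaks at the wrists. Synchrony is the time
#' difference between the left- and right-wrist peaks of a phase,
#' normalized by the cycle duration, averaged over cycles; 0 means the arms
#' move together, 0.5 means perfect alternation. Only straight-driving
#' parts of the recording are used (pass the `"straight"` blocks from
#' [segment_drive_phases()]); during turning the two rims are intentionally
#' driven asymmetrically.
#'
#' The push phase carries the dominant peaks and provides the reported
#' feature; the smaller release-phase peaks between consecutive pushes are
#' measured the same way and reported as a diagnostic.
#'
#' @param left_mag,right_mag wrist acceleration-magnitude series, g.
#' @param fs sampling rate, Hz.
#' @param straight_segments tibble with `start`/`end` columns (half-open,
#'   0-based samples) selecting straight-driving blocks; `NULL` uses the
#'   whole series.
#' @param min_cycle_s minimum credible push-cycle duration, s.
#' @return one-row tibble: `armsync` (push-phase lag fraction, in
#'   `[0, 0.5]`), `armsync_release` (release-phase diagnostic, `NA` when no
#'   release peaks are detectable), `n_cycles`, `cycle_dur_s`.
#' @export
arm_synchrony <- function(left_mag, right_mag, fs, straight_segments = NULL,
                          min_cycle_s = 0.5) {
  if (length(left_mag) != length(right_mag)) {
    stop("left and right series must have equal length", call. = FALSE)
  }
  check_positive(fs, "fs")
  if (is.null(straight_segments)) {
    straight_segments <- tibble::tibble(
      start = 0L, end = length(left_mag)
    )
  }
  min_gap <- as.integer(round(min_cycle_s * fs * 0.8))

  push_lags <- numeric(0)
  release_lags <- numeric(0)
  cycles <- numeric(0)
  for (b in seq_len(nrow(straight_segments))) {
    idx <- seq.int(straight_segments$start[b] + 1L, straight_segments$end[b])
    L <- moving_average(left_mag[idx], 7L)
    R <- moving_average(right_mag[idx], 7L)

    pk <- function(x) {
      thr <- median(x) + 0.4 * (max(x) - median(x))
      find_peaks(x, threshold = thr, min_gap = min_gap)
    }
    pl <- pk(L)
    pr <- pk(R)
    if (length(pl) < 2L || length(pr) < 2L) next

    # leading wrist = the one with more / earlier peaks drives the cycle grid
    lead <- if (length(pr) >= length(pl)) pr else pl
    other <- if (identical(lead, pr)) pl else pr
    cyc <- median(diff(lead)) / fs
    if (!is.finite(cyc) || cyc <= 0) next

    for (p in lead) {
      j <- other[which.min(abs(other - p))]
      lag <- abs(j - p) / fs
      if (lag <= cyc / 2) {
        push_lags <- c(push_lags, lag / cyc)
        cycles <- c(cycles, cyc)
      }
    }

    # release phase: the secondary bump between consecutive pushes
    rel_peak <- function(x, peaks) {
      vapply(seq_len(length(peaks) - 1L), function(k) {
        lo <- peaks[k] + min_gap %/% 2L
        hi <- peaks[k + 1L] - min_gap %/% 2L
        if (lo >= hi) return(NA_real_)
        seg <- x[lo:hi]
        lo + which.max(seg) - 1L
      }, numeric(1))
    }
    rl <- rel_peak(L, pl)
    rr <- rel_peak(R, pr)
    nrel <- min(length(rl), length(rr))
    if (nrel >= 1L) {
      d <- abs(rl[seq_len(nrel)] - rr[seq_len(nrel)]) / fs
      d <- d[is.finite(d) & d <= cyc / 2]
      release_lags <- c(release_lags, d / cyc)
    }
  }

  if (length(push_lags) < 2L) {
    stop("fewer than 2 push cycles detected in the straight segments",
      call. = FALSE
    )
  }
  tibble::tibble(
    armsync = mean(push_lags),
    armsync_release = if (length(release_lags) > 0) {
      mean(release_lags)
    } else {
      NA_real_
    },
    n_cycles = length(push_lags),
    cycle_dur_s = mean(cycles)
  )
}
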