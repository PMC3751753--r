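# Piecewise-linear time-series segmentation: bottom-up merging and the
# online Sliding-Window-And-Bottom-up (SWAB) variant, used to split
# wheelchair-propulsion recordings into straight-driving and turning.

# Sum of squared residuals of the least-squares line through x[i..j].
segment_sse <- function(x, i, j) {
  n <- j - i + 1L
  if (n <= 2L) return(0)
  t <- seq_len(n)
  y <- x[i:j]
  tm <- (n + 1) / 2
  ym <- mean(y)
  st2 <- sum((t - tm)^2)
  b <- sum((t - tm) * (y - ym)) / st2
  sum((y - ym - b * (t - tm))^2)
}

#' Bottom-up piecewise-linear segmentation
#'
#' Starts from the finest segmentation (two-sample segments) and repeatedly
#' merges the adjacent pair whose merged least-squares line has the smallest
#' residual error, until no merge keeps the per-segment squared residual
#' below `max_error`.
#'
#' @param x numeric series.
#' @param max_error maximum allowed sum of squared residuals of the linear
#'   fit within one segment.
#' @return integer vector of segment start indices (1-based), beginning
#'   with 1; segment `k` spans `starts[k] .. starts[k+1] - 1`.
#' @export
bottom_up_breakpoints <- function(x, max_error) {
  n <- length(x)
  if (n <= 2L) return(1L)
  starts <- seq.int(1L, n, by = 2L)
  if (starts[length(starts)] == n) starts <- starts[-length(starts)]
  ends <- c(starts[-1L] - 1L, n)

  merge_cost <- function(k) { # cost of merging segment k with k+1
    segment_sse(x, starts[k], ends[k + 1L])
  }
  costs <- vapply(seq_len(length(starts) - 1L), merge_cost, numeric(1))

  while (length(starts) > 1L && min(costs) <= max_error) {
    k <- which.min(costs)
    starts <- starts[-(k + 1L)]
    ends <- ends[-k]
    costs <- costs[-k]
    if (k > 1L) costs[k - 1L] <- merge_cost(k - 1L)
    if (k <= length(starts) - 1L) costs[k] <- merge_cost(k)
    if (length(starts) == 1L) break
  }
  starts
}

#' SWAB segmentation
#'
#' Online variant of bottom-up segmentation: a buffer holding roughly
#' `buffer_size` samples is segmented bottom-up, the leftmost segment is
#' emitted, and the buffer slides forward by the emitted length. When the
#' buffer spans the whole series the result equals
#' [bottom_up_breakpoints()] exactly.
#'
#' @inheritParams bottom_up_breakpoints
#' @param buffer_size number of samples held in the working buffer;
#'   `Inf` processes the whole series in one bottom-up pass.
#' @return integer vector of segment start indices (1-based).
#' @export
swab_breakpoints <- function(x, max_error, buffer_size = Inf) {
  n <- length(x)
  if (buffer_size >= n) return(bottom_up_breakpoints(x, max_error))
  buffer_size <- max(6L, as.integer(buffer_size))

  out <- integer(0)
  lo <- 1L # series index of buffer start
  hi <- min(n, lo + buffer_size - 1L)
  repeat {
    bp <- bottom_up_breakpoints(x[lo:hi], max_error)
    if (hi == n) {
      out <- c(out, lo + bp - 1L)
      break
    }
    # emit leftmost segment, slide buffer
    seg_len <- if (length(bp) > 1L) bp[2L] - 1L else hi - lo + 1L
    out <- c(out, lo)
    lo <- lo + seg_len
    hi <- min(n, lo + buffer_size - 1L)
    if (lo >= n) break
  }
  unique(out)
}

# Centred rolling-std envelope of a magnitude series, decimated to
# `env_fs`. Local variability tracks propulsion activity: high while
# pushing, low while coasting through the turn.
activity_envelope <- function(mag, fs, env_fs = 10, window_s = 1.0) {
  n <- length(mag)
  k <- min(n, max(3L, as.integer(round(window_s * fs))))
  v <- rolling_sd(mag, k) # one value per window start
  half <- (k - 1L) %/% 2L # centre-align, replicate edges
  centred <- c(rep(v[1L], half), v,
               rep(v[length(v)], n - length(v) - half))
  step <- max(1L, as.integer(round(fs / env_fs)))
  idx <- seq.int(1L, n, by = step)
  list(env = centred[idx], idx = idx, env_fs = fs / step)
}

#' Segment a propulsion recording into straight-driving and turning
#'
#' Computes a 10 Hz moving-RMS activity envelope of the acceleration
#' magnitude, segments it piecewise-linearly with SWAB, labels each segment
#' by its mean activity (turning is the low-activity gap between the two
#' high-activity straight-driving blocks), and merges adjacent segments
#' with the same label into regime blocks.
#'
#' @param mag acceleration-magnitude series, g.
#' @param fs sampling rate, Hz.
#' @param max_error SWAB residual cap on the envelope; `NULL` scales it to
#'   the envelope's short-term variability.
#' @param buffer_s SWAB buffer length, s.
#' @return tibble of regime blocks: `start`, `end` (half-open, 0-based
#'   samples), `start_s`, `end_s`, `regime` (`"straight"` or `"turn"`),
#'   `mean_activity` (g). A flat series yields a single `"straight"` block.
#' @export
segment_drive_phases <- function(mag, fs, max_error = NULL, buffer_s = 8) {
  if (length(mag) == 0L) stop("`mag` is empty", call. = FALSE)
  check_positive(fs, "fs")
  ae <- activity_envelope(mag, fs)
  env <- ae$env
  n_env <- length(env)

  if (is.null(max_error)) {
    # allowance ~ local (high-pass) envelope variability over a few seconds
    local_var <- median((env - moving_average(env, 11L))^2)
    max_error <- max(local_var, 1e-12) * 3 * ae$env_fs
  }
  bp <- swab_breakpoints(env, max_error,
    buffer_size = as.integer(buffer_s * ae$env_fs)
  )
  seg_start <- bp
  seg_end <- c(bp[-1L] - 1L, n_env)
  means <- vapply(
    seq_along(seg_start),
    function(k) mean(env[seg_start[k]:seg_end[k]]),
    numeric(1)
  )

  rng <- range(means)
  if (diff(rng) < 1e-8 || rng[2L] < 2 * rng[1L]) {
    labels <- rep("straight", length(means)) # no contrast: one regime
  } else {
    thr <- mean(rng)
    labels <- ifelse(means < thr, "turn", "straight")
  }

  # merge adjacent same-label segments into regime blocks
  block_id <- cumsum(c(1L, as.integer(labels[-1L] != labels[-length(labels)])))
  blocks <- tibble::tibble(
    id = block_id, s = seg_start, e = seg_end, m = means
  ) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      s = min(.data$s), e = max(.data$e), m = mean(.data$m),
      .groups = "drop"
    )
  labels_b <- labels[!duplicated(block_id)]

  # refine regime boundaries: SWAB segments place a boundary somewhere on
  # the activity ramp between regimes; snap each internal boundary to the
  # nearest crossing of the envelope through the mid-activity threshold
  env_starts <- blocks$s
  if (length(env_starts) > 1L && diff(rng) >= 1e-8) {
    thr <- mean(rng)
    crossings <- which(diff(env >= thr) != 0L) + 1L
    max_snap <- as.integer(round(2 * ae$env_fs))
    for (j in seq_along(env_starts)[-1L]) {
      if (length(crossings) == 0L) break
      d <- abs(crossings - env_starts[j])
      if (min(d) <= max_snap) {
        env_starts[j] <- crossings[which.min(d)]
      }
    }
  }

  # map envelope indices back to raw samples (half-open, 0-based)
  raw_start <- ae$idx[env_starts] - 1L
  raw_end <- c(raw_start[-1L], length(mag))
  tibble::tibble(
    start = as.integer(raw_start), end = as.integer(raw_end),
    start_s = raw_start / fs, end_s = raw_end / fs,
    regime = labels_b, mean_activity = blocks$m
  )
}
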