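# Shared fixture builders. All fixtures are generated in code at test time.

fs_default <- 100

# trace with given accel / gyro matrices and sensible defaults
make_trace <- function(accel = NULL, gyro = NULL, n = 200, fs = fs_default,
                       placement = "wrist_R") {
  if (is.null(accel)) accel <- matrix(c(0, 0, 1), n, 3, byrow = TRUE)
  if (is.null(gyro)) gyro <- matrix(0, nrow(accel), 3)
  imu_trace(accel, gyro, fs, placement = placement)
}

# random 2 s trace for oracle comparisons
random_trace <- function(seed, n = 200, fs = fs_default) {
  withr::with_seed(seed, {
    accel <- matrix(rnorm(n * 3, 0, 0.5), n, 3)
    accel[, 3] <- accel[, 3] + 1
    gyro <- matrix(rnorm(n * 3, 0, 40), n, 3)
    imu_trace(accel, gyro, fs)
  })
}

# a uniformly random 3-D rotation matrix
random_rotation <- function(seed) {
  withr::with_seed(seed, {
    M <- matrix(rnorm(9), 3, 3)
    qr_ <- qr(M)
    Q <- qr.Q(qr_)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
  })
}

rotate_trace <- function(trace, R) {
  imu_trace(
    accel_mat(trace) %*% t(R),
    gyro_mat(trace) %*% t(R),
    trace_fs(trace),
    placement = trace_placement(trace)
  )
}

accel_mat <- function(tr) cbind(tr$ax_g, tr$ay_g, tr$az_g)
gyro_mat <- function(tr) cbind(tr$gx_dps, tr$gy_dps, tr$gz_dps)

# independent direct-DFT oracle (O(n^2)), DC removed, positive bins
dft_energy_oracle <- function(x, fs) {
  x <- x - mean(x)
  n <- length(x)
  n_pos <- floor(n / 2)
  freq <- (1:n_pos) * fs / n
  energy <- vapply(1:n_pos, function(k) {
    re <- sum(x * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(x * sin(-2 * pi * k * (0:(n - 1)) / n))
    re^2 + im^2
  }, numeric(1))
  list(freq = freq, energy = energy)
}

oracle_dominant_frequency <- function(x, fs) {
  o <- dft_energy_oracle(x, fs)
  o$freq[which.max(o$energy)]
}

oracle_smoothness <- function(x, fs, bandwidth = 0.2) {
  o <- dft_energy_oracle(x, fs)
  df <- o$freq[which.max(o$energy)]
  res <- fs / length(x)
  in_band <- if (res > bandwidth) {
    o$freq == df
  } else {
    abs(o$freq - df) <= bandwidth / 2 + res / 2 + 1e-9
  }
  sum(o$energy[in_band]) / sum(o$energy)
}

# naive per-sample loops for the scalar features
oracle_mi <- function(acc) {
  s <- 0
  for (i in seq_len(nrow(acc))) {
    s <- s + sqrt(acc[i, 1]^2 + acc[i, 2]^2 + acc[i, 3]^2)
  }
  s / nrow(acc)
}

oracle_miv <- function(acc) {
  m <- numeric(nrow(acc))
  for (i in seq_len(nrow(acc))) {
    m[i] <- sqrt(acc[i, 1]^2 + acc[i, 2]^2 + acc[i, 3]^2)
  }
  mb <- mean(m)
  sqrt(sum((m - mb)^2) / length(m))
}

oracle_are <- function(gyr) {
  s <- 0
  for (i in seq_len(nrow(gyr))) {
    s <- s + gyr[i, 1]^2 + gyr[i, 2]^2 + gyr[i, 3]^2
  }
  s / nrow(gyr)
}

oracle_rang <- function(gyr) {
  m <- sqrt(rowSums(gyr^2))
  ms <- sort(m)
  ms[length(ms)] - ms[1]
}

# filtered magnitude convenience used across recovery tests
fmag <- function(trace, channel = "accel") {
  magnitude(lowpass_trace(trace), channel)
}
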