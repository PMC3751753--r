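test_that("magnitude is the per-sample Euclidean norm", {
  tr <- make_trace(accel = matrix(c(0, 0, 1), 5, 3, byrow = TRUE))
  expect_equal(magnitude(tr, "accel"), rep(1, 5))

  tr2 <- make_trace(accel = matrix(c(0.6, 0.8, 0), 5, 3, byrow = TRUE))
  expect_equal(magnitude(tr2, "accel"), rep(1, 5))

  tr3 <- random_trace(1)
  expect_equal(
    magnitude(tr3, "gyro"),
    sqrt(tr3$gx_dps^2 + tr3$gy_dps^2 + tr3$gz_dps^2)
  )
  expect_true(all(magnitude(tr3, "accel") >= 0))
})

test_that("magnitude is invariant to fixed axis rotations", {
  for (seed in 1:10) {
    tr <- random_trace(seed)
    R <- random_rotation(seed + 100)
    tr_rot <- rotate_trace(tr, R)
    expect_lt(max(abs(magnitude(tr, "accel") - magnitude(tr_rot, "accel"))),
      1e-9
    )
    expect_lt(max(abs(magnitude(tr, "gyro") - magnitude(tr_rot, "gyro"))),
      1e-9
    )
  }
})

test_that("lowpass has unit DC gain and preserves the deep passband", {
  x <- rep(1, 500)
  expect_lt(max(abs(lowpass(x, 100) - 1)), 1e-9)

  t <- (0:999) / 100
  s2 <- sin(2 * pi * 2 * t)
  y2 <- lowpass(s2, 100)
  expect_lt(abs(max(abs(y2[100:900])) / max(abs(s2[100:900])) - 1), 0.01)
})

test_that("lowpass attenuates near-Nyquist content and is idempotent in-band", {
  t <- (0:999) / 100
  s48 <- sin(2 * pi * 48 * t)
  expect_lt(sd(lowpass(s48, 100)), sd(s48))

  s2 <- sin(2 * pi * 2 * t)
  once <- lowpass(s2, 100)
  twice <- lowpass(once, 100)
  expect_lt(
    abs(max(abs(twice[100:900])) / max(abs(once[100:900])) - 1), 0.02
  )
})

test_that("lowpass rejects cutoffs at or beyond Nyquist", {
  expect_error(lowpass(rnorm(100), 100, cutoff = 50), "Nyquist")
  expect_error(lowpass(rnorm(100), 100, cutoff = 60), "Nyquist")
})

test_that("task boundaries are recovered from the labeling trace", {
  ivs <- list(c(2, 8), c(11, 15), c(18, 25))
  tr <- simulate_labeling_trace(ivs, fs = 100, seed = 3)
  out <- detect_task_boundaries(tr)
  expect_equal(nrow(out), 3L)
  for (i in 1:3) {
    expect_lt(abs(out$start_s[i] - ivs[[i]][1]), 0.2)
    expect_lt(abs(out$end_s[i] - ivs[[i]][2]), 0.2)
  }
  expect_true(all(out$start < out$end))
  expect_true(all(diff(out$start) > 0))
  # non-overlap of consecutive intervals
  expect_true(all(out$end[-3] <= out$start[-1]))
})

test_that("a flat noise labeling trace yields no intervals", {
  tr <- simulate_labeling_trace(list(), fs = 100, seed = 4)
  out <- detect_task_boundaries(tr)
  expect_equal(nrow(out), 0L)
})

test_that("an end marker before any start marker is an error", {
  # double burst first, then a single burst: malformed labeling
  withr::with_seed(9, {
    n <- 1200
    gx <- rnorm(n, 0, 3)
    burst <- 500 * sin(pi * seq(0, 1, length.out = 12))
    gx[200:211] <- gx[200:211] + burst
    gx[235:246] <- gx[235:246] + burst # double burst = end
    gx[800:811] <- gx[800:811] + burst # lone single = start
    tr <- imu_trace(
      cbind(rnorm(n, 0, 0.01), rnorm(n, 0, 0.01), 1 + rnorm(n, 0, 0.01)),
      cbind(gx, rnorm(n, 0, 3), rnorm(n, 0, 3)),
      100,
      placement = "labeler"
    )
  })
  expect_error(detect_task_boundaries(tr), "unmatched")
})

test_that("the synchronization clap is located at the largest transient", {
  x <- rep(1, 1000)
  x[513] <- 4 # 0-based sample 512
  expect_equal(detect_sync_clap(x, 100), 512L)

  expect_error(detect_sync_clap(rep(1, 100), 100), "no clap")

  x2 <- rep(1, 1000)
  x2[301] <- 3
  x2[701] <- 4
  expect_equal(detect_sync_clap(x2, 100), 700L)
})
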