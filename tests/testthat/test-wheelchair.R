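fs <- 100

test_that("SWAB with a full-length buffer equals pure bottom-up", {
  withr::with_seed(11, {
    x <- c(
      seq(0, 1, length.out = 30) + rnorm(30, 0, 0.02),
      seq(1, 0.2, length.out = 40) + rnorm(40, 0, 0.02),
      rep(0.2, 30) + rnorm(30, 0, 0.02)
    )
  })
  bu <- bottom_up_breakpoints(x, max_error = 0.05)
  sw <- swab_breakpoints(x, max_error = 0.05, buffer_size = Inf)
  expect_identical(sw, bu)
  sw2 <- swab_breakpoints(x, max_error = 0.05, buffer_size = length(x))
  expect_identical(sw2, bu)
})

test_that("a constant series yields a single segment", {
  expect_equal(bottom_up_breakpoints(rep(2, 50), 0.01), 1L)
  ph <- segment_drive_phases(rep(1, 800), fs)
  expect_equal(nrow(ph), 1L)
  expect_equal(ph$regime, "straight")
  expect_equal(ph$start, 0L)
  expect_equal(ph$end, 800L)
})

test_that("segments partition the series", {
  withr::with_seed(2, x <- cumsum(rnorm(120)))
  bp <- swab_breakpoints(x, max_error = 2, buffer_size = 40)
  expect_equal(bp[1], 1L)
  expect_true(all(diff(bp) > 0))
  expect_true(all(bp <= length(x)))
})

test_that("straight-turn-straight wheelchair layout is recovered", {
  for (seed in c(1, 5, 9)) {
    w <- simulate_wheelchair(lag_frac = 0.1, turn_dur = 3, seed = seed)
    mag <- (fmag(w$traces$wrist_L) + fmag(w$traces$wrist_R)) / 2
    ph <- segment_drive_phases(mag, fs)
    expect_equal(nrow(ph), 3L)
    expect_equal(ph$regime, c("straight", "turn", "straight"))
    bp_true <- w$truth$segment_breakpoints
    expect_lt(abs(ph$start[2] - bp_true[2]) / fs, 0.5)
    expect_lt(abs(ph$start[3] - bp_true[3]) / fs, 0.5)
    # turn block spans roughly the programmed 3 s
    expect_lt(abs((ph$end[2] - ph$start[2]) / fs - 3), 1.0)
  }
})

test_that("arm synchrony recovers programmed lag fractions", {
  for (lag in c(0, 0.1, 0.25)) {
    for (seed in c(2, 7)) {
      w <- simulate_wheelchair(lag_frac = lag, seed = seed)
      lm_ <- fmag(w$traces$wrist_L)
      rm_ <- fmag(w$traces$wrist_R)
      ph <- segment_drive_phases((lm_ + rm_) / 2, fs)
      sync <- arm_synchrony(lm_, rm_, fs,
        straight_segments = ph[ph$regime == "straight", ]
      )
      expect_lt(abs(sync$armsync - lag), 0.02)
      expect_gte(sync$armsync, 0)
      expect_lte(sync$armsync, 0.5)
    }
  }
})

test_that("identical traces give zero lag and the release lag is reported", {
  w <- simulate_wheelchair(lag_frac = 0, seed = 3)
  m <- fmag(w$traces$wrist_R)
  sync <- arm_synchrony(m, m, fs)
  expect_equal(sync$armsync, 0)
  expect_true(is.finite(sync$armsync_release) || is.na(sync$armsync_release))
})

test_that("fewer than two push cycles is an explicit failure", {
  expect_error(
    arm_synchrony(rep(1, 300), rep(1, 300), fs),
    "push cycles"
  )
})

test_that("wheelchair generator validates lag and records ground truth", {
  expect_error(simulate_wheelchair(lag_frac = 0.6), "lag_frac")
  w <- simulate_wheelchair(lag_frac = 0.1, turn_dur = 3, n_cycles = 6L,
    seed = 1
  )
  bp <- w$truth$segment_breakpoints
  expect_equal((bp[3] - bp[2]) / fs, 3)
  expect_equal(bp[1], 0L)
  expect_equal(bp[4], trace_length(w$traces$hip))
  # left peaks lag right peaks by lag*cycle
  expect_equal(
    w$truth$push_peaks$L - w$truth$push_peaks$R,
    rep(10L, length(w$truth$push_peaks$R))
  )
})
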