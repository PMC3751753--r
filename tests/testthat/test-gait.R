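fs <- 100

test_that("heel strikes of a clean synthetic walk are recovered exactly", {
  g <- simulate_gait(n_steps = 10L, noise_sd = 0.02, seed = 2)
  for (ft in c("L", "R")) {
    trace <- g$traces[[paste0("foot_", ft)]]
    ev <- detect_heel_strikes(fmag(trace), fs)
    truth <- g$truth$heel_strikes[[ft]]
    expect_length(ev$strikes, length(truth))
    expect_lte(max(abs(ev$strikes - truth)), 2)
    # lift-offs interleave with strikes
    k <- seq_along(ev$lift_offs)
    expect_true(all(ev$lift_offs > ev$strikes[k]))
    expect_true(all(ev$lift_offs < ev$strikes[k + 1L]))
  }
})

test_that("a flat 1 g series produces no gait events", {
  ev <- detect_heel_strikes(rep(1, 1000), fs)
  expect_length(ev$strikes, 0L)
})

test_that("detection rate does not increase with sensor noise", {
  rate_at <- function(noise_sd) {
    hits <- vapply(1:6, function(seed) {
      g <- simulate_gait(n_steps = 8L, noise_sd = noise_sd, seed = seed)
      ev <- detect_heel_strikes(fmag(g$traces$foot_L), fs)
      truth <- g$truth$heel_strikes$L
      sum(vapply(truth, function(tt) any(abs(ev$strikes - tt) <= 2), TRUE))
    }, numeric(1))
    sum(hits)
  }
  rates <- c(rate_at(0.01), rate_at(0.05), rate_at(0.25))
  expect_true(all(diff(rates) <= 0))
})

test_that("gait durations from hand-listed events match direct arithmetic", {
  el <- gait_events(
    strikes = c(0L, 100L, 200L), lift_offs = c(60L, 160L), fs = fs
  )
  er <- gait_events(
    strikes = c(50L, 150L, 250L), lift_offs = c(110L, 210L), fs = fs
  )
  gd <- gait_durations(el, er, fs)
  expect_equal(gd$T_step_avg, 1.0)
  expect_equal(gd$T_step_ratio, 1.0)
  expect_equal(gd$T_stance_avg, 0.6)
  expect_equal(gd$T_stance_ratio, 1.0)
})

test_that("symmetric and asymmetric step programs are recovered", {
  g <- simulate_gait(
    step_dur_left = 1.2, step_dur_right = 1.2, stance_frac = 0.6,
    n_steps = 10L, seed = 4
  )
  evl <- detect_heel_strikes(fmag(g$traces$foot_L), fs)
  evr <- detect_heel_strikes(fmag(g$traces$foot_R), fs)
  gd <- gait_durations(evl, evr, fs)
  expect_lt(abs(gd$T_step_avg - 1.2), 0.02 * 1.2)
  expect_lt(abs(gd$T_step_ratio - 1.0), 0.02)
  expect_lt(abs(gd$T_stance_ratio - 1.0), 0.02)

  g2 <- simulate_gait(step_dur_left = 1.0, step_dur_right = 1.4, seed = 5)
  ev2l <- detect_heel_strikes(fmag(g2$traces$foot_L), fs)
  ev2r <- detect_heel_strikes(fmag(g2$traces$foot_R), fs)
  gd2 <- gait_durations(ev2l, ev2r, fs)
  expect_lt(abs(gd2$T_step_ratio - 1.4), 0.05)
})

test_that("too few strikes on one foot is an explicit error naming the foot", {
  el <- gait_events(strikes = c(0L, 100L), lift_offs = 60L, fs = fs)
  er <- gait_events(strikes = 50L, lift_offs = integer(0), fs = fs)
  expect_error(gait_durations(el, er, fs), "right")
})

test_that("simulate_gait validates its inputs and its ground truth", {
  expect_error(simulate_gait(stance_frac = 1.2), "stance_frac")
  expect_error(simulate_gait(n_steps = 1L), "n_steps")

  g <- simulate_gait(n_steps = 10L, seed = 1)
  n <- trace_length(g$traces$foot_L)
  for (ft in c("L", "R")) {
    expect_length(g$truth$heel_strikes[[ft]], 10L)
    expect_true(all(g$truth$heel_strikes[[ft]] >= 0))
    expect_true(all(g$truth$heel_strikes[[ft]] < n))
    expect_true(all(
      g$truth$stance_durations[[ft]] < g$truth$step_durations[[ft]]
    ))
  }
  expect_equal(
    g$truth$step_durations$L / g$truth$step_durations$R,
    rep(1, 9)
  )
})
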