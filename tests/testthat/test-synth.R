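test_that("generators are bit-deterministic given a seed", {
  a <- simulate_manual_task(impairment_profile(0), "cards", seed = 7)
  b <- simulate_manual_task(impairment_profile(0), "cards", seed = 7)
  expect_identical(a, b)

  g1 <- simulate_gait(seed = 3)
  g2 <- simulate_gait(seed = 3)
  expect_identical(g1, g2)

  w1 <- simulate_wheelchair(seed = 5)
  w2 <- simulate_wheelchair(seed = 5)
  expect_identical(w1, w2)

  s1 <- simulate_session(impairment_profile(0.4, "left"), seed = 2)
  s2 <- simulate_session(impairment_profile(0.4, "left"), seed = 2)
  expect_identical(s1, s2)

  # and the global RNG stream is left untouched
  withr::with_seed(1, {
    before <- rnorm(1)
  })
  withr::with_seed(1, {
    invisible(simulate_manual_task(impairment_profile(0.5), seed = 99))
    after <- rnorm(1)
  })
  expect_identical(before, after)
})

test_that("impairment lengthens the active window monotonically", {
  a0 <- simulate_manual_task(impairment_profile(0), "cards", seed = 13)
  a1 <- simulate_manual_task(impairment_profile(1), "cards", seed = 13)
  expect_gt(a1$truth$active_s, a0$truth$active_s)
  expect_gt(trace_length(a1$trace), trace_length(a0$trace))
})

test_that("mid-impairment smoothness lies between the extremes", {
  mean_sm <- function(level) {
    mean(vapply(1:50, function(seed) {
      s <- simulate_manual_task(impairment_profile(level), "cards",
        seed = seed
      )
      as.numeric(smoothness(magnitude(s$trace, "accel"), 100))
    }, numeric(1)))
  }
  s0 <- mean_sm(0)
  s5 <- mean_sm(0.5)
  s1 <- mean_sm(1)
  expect_gt(s5, s1)
  expect_lt(s5, s0)
})

test_that("quiescent segments sit near 1 g and all samples are finite", {
  s <- simulate_manual_task(impairment_profile(0.5), "cards", seed = 4)
  tr <- s$trace
  expect_true(all(is.finite(as.matrix(tr[, 2:7]))))
  lead <- magnitude(tr, "accel")[1:100]
  expect_lt(abs(mean(lead) - 1), 3 * 0.01)
  iv <- s$truth$active_interval
  expect_gte(iv[1], 0)
  expect_lte(iv[2], trace_length(tr))
})

test_that("labeling trace carries one single and one double burst per task", {
  ivs <- list(c(2, 6), c(9, 12), c(15, 20))
  tr <- simulate_labeling_trace(ivs, fs = 100, seed = 5)
  peaks <- imucap:::detect_bursts(tr$gx_dps, 100)
  # 3 single starts + 3 double ends = 9 bursts
  expect_equal(length(peaks), 9L)

  flat <- simulate_labeling_trace(list(), fs = 100, seed = 6)
  expect_equal(length(imucap:::detect_bursts(flat$gx_dps, 100)), 0L)

  expect_error(
    simulate_labeling_trace(list(c(0, 5), c(4, 8)), seed = 1),
    "non-overlapping"
  )
  expect_error(simulate_labeling_trace(list(c(3, 2)), seed = 1), "start < end")
})

test_that("noise-free ratings are an exact affine function of the features", {
  sess <- simulate_session(impairment_profile(0.5, "left"),
    rating_noise_sd = 0, seed = 8
  )
  for (i in seq_len(nrow(sess$instances))) {
    tc <- sess$instances$task_class[i]
    w <- default_rating_weights(tc)
    f <- sess$instances$features[[i]]
    expect_equal(
      sess$instances$target[i],
      unname(w[1] + sum(w[-1] * f)),
      tolerance = 1e-12
    )
  }
  expect_true(all(sess$instances$target >= 0 & sess$instances$target <= 1))
})

test_that("ratings improve over weeks when a recovery trend is set", {
  prof <- impairment_profile(0.8, "left", week_trend = 0.1)
  targets <- vapply(1:4, function(w) {
    s <- simulate_session(prof,
      week = w, task_list = default_task_list()[1, ],
      rating_noise_sd = 0, seed = 40 + w
    )
    mean(s$instances$target_true)
  }, numeric(1))
  expect_true(all(diff(targets) > 0))
})

test_that("rating weight dimension mismatches are rejected by task class", {
  bad <- list(cards = c("(Intercept)" = 0.5, TIME = -0.1))
  expect_error(
    simulate_session(impairment_profile(0.2),
      task_list = default_task_list()[1, ],
      rating_weights = bad, seed = 1
    ),
    "feature layout"
  )
})

test_that("generator preconditions are enforced with named messages", {
  expect_error(
    simulate_manual_task(impairment_profile(0), fs = -1),
    "fs"
  )
  expect_error(
    simulate_manual_task(impairment_profile(0), duration_hint = 0),
    "duration_hint"
  )
  expect_error(impairment_profile(1.4), "level")
  expect_error(impairment_profile(0.5, week_trend = -1), "week_trend")
})
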