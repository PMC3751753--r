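test_that("movement intensity and its variation match hand values", {
  acc1 <- matrix(c(0, 0, 1), 10, 3, byrow = TRUE)
  expect_equal(movement_intensity(acc1), 1.0)
  expect_equal(movement_intensity_variation(acc1), 0.0)

  # half the samples at magnitude 0.5, half at 1.5: MI = 1, MIV = 0.5
  acc2 <- rbind(
    matrix(c(0, 0, 0.5), 10, 3, byrow = TRUE),
    matrix(c(0, 0, 1.5), 10, 3, byrow = TRUE)
  )
  expect_equal(movement_intensity(acc2), 1.0)
  expect_equal(movement_intensity_variation(acc2), 0.5)
})

test_that("rotation energy and angular-velocity range match hand values", {
  gyr <- matrix(c(10, 0, 0), 8, 3, byrow = TRUE)
  expect_equal(average_rotation_energy(gyr), 100)
  expect_equal(range_angular_velocity(gyr), 0)

  ramp <- cbind(seq(0, 100, length.out = 50), 0, 0)
  expect_equal(range_angular_velocity(ramp), 100)
  expect_equal(average_rotation_energy(matrix(0, 5, 3)), 0)
})

test_that("scalar features match naive-loop oracles on random traces", {
  for (seed in 1:25) {
    tr <- random_trace(seed)
    acc <- accel_mat(tr)
    gyr <- gyro_mat(tr)
    expect_equal(movement_intensity(acc), oracle_mi(acc), tolerance = 1e-12)
    expect_equal(movement_intensity_variation(acc), oracle_miv(acc),
      tolerance = 1e-12
    )
    expect_equal(average_rotation_energy(gyr), oracle_are(gyr),
      tolerance = 1e-9
    )
    expect_equal(range_angular_velocity(gyr), oracle_rang(gyr),
      tolerance = 1e-12
    )
  }
})

test_that("dominant frequency finds tones and breaks ties downward", {
  fs <- 100
  t <- (0:999) / fs
  x1 <- 1 + 0.3 * sin(2 * pi * 2 * t)
  expect_lt(abs(dominant_frequency(x1, fs) - 2), 0.1 + 1e-9)

  x2 <- 1 + 0.3 * sin(2 * pi * 2 * t) + 0.1 * sin(2 * pi * 5 * t)
  expect_lt(abs(dominant_frequency(x2, fs) - 2), 0.1 + 1e-9)

  # exactly equal-energy tones on exact bins: tie broken to the lower one
  x3 <- 0.2 * sin(2 * pi * 2 * t) + 0.2 * sin(2 * pi * 5 * t)
  expect_equal(dominant_frequency(x3, fs), 2)
})

test_that("spectral smoothness is 1 for a tone and interpolates with noise", {
  fs <- 100
  t <- (0:999) / fs
  tone <- 1 + 0.3 * sin(2 * pi * 2 * t)
  expect_gte(as.numeric(smoothness(tone, fs)), 0.99)

  withr::with_seed(5, {
    noise <- rnorm(1000, 0, sqrt(mean((0.3 * sin(2 * pi * 2 * t))^2)))
  })
  mixed <- tone + noise
  sm_tone <- as.numeric(smoothness(tone, fs))
  sm_noise <- as.numeric(smoothness(1 + noise, fs))
  sm_mixed <- as.numeric(smoothness(mixed, fs))
  expect_gt(sm_mixed, sm_noise)
  expect_lt(sm_mixed, sm_tone)
})

test_that("white-noise smoothness is small and bounded below by the band fraction", {
  fs <- 100
  sms <- vapply(1:50, function(seed) {
    withr::with_seed(seed, as.numeric(smoothness(rnorm(1000), fs)))
  }, numeric(1))
  # flat-spectrum floor: band width / positive bandwidth; selection of the
  # max bin biases the mean above that floor but it must stay small
  expect_gt(mean(sms), 0.2 / 50)
  expect_lt(mean(sms), 0.05)
  expect_true(all(sms >= 0 & sms <= 1))
})

test_that("smoothness flags short series where the band collapses to one bin", {
  fs <- 100
  x <- 1 + sin(2 * pi * 2 * (0:299) / fs) # 3 s < 5 s resolution limit
  sm <- smoothness(x, fs)
  expect_true(attr(sm, "band_limited"))
  x10 <- 1 + sin(2 * pi * 2 * (0:999) / fs)
  expect_false(attr(smoothness(x10, fs), "band_limited"))
})

test_that("DF and SM match a direct-DFT oracle on random traces", {
  fs <- 100
  for (seed in 1:20) {
    x <- magnitude(random_trace(seed), "accel")
    expect_equal(dominant_frequency(x, fs), oracle_dominant_frequency(x, fs),
      tolerance = 1e-9
    )
    expect_equal(as.numeric(smoothness(x, fs)), oracle_smoothness(x, fs),
      tolerance = 1e-9
    )
  }
})

test_that("all features are invariant to a fixed sensor rotation", {
  fs <- 100
  for (seed in c(2, 12)) {
    s <- simulate_manual_task(impairment_profile(0.3), "cards", seed = seed)
    R <- random_rotation(seed)
    tr <- s$trace
    tr_rot <- rotate_trace(tr, R)
    a <- magnitude(tr, "accel")
    b <- magnitude(tr_rot, "accel")
    expect_equal(movement_intensity(accel_mat(tr)),
      movement_intensity(accel_mat(tr_rot)),
      tolerance = 1e-9
    )
    expect_equal(dominant_frequency(a, fs), dominant_frequency(b, fs),
      tolerance = 1e-9
    )
    expect_equal(as.numeric(smoothness(a, fs)),
      as.numeric(smoothness(b, fs)),
      tolerance = 1e-9
    )
    expect_equal(range_angular_velocity(gyro_mat(tr)),
      range_angular_velocity(gyro_mat(tr_rot)),
      tolerance = 1e-9
    )
  }
})

test_that("SM stays within [0,1] and MIV obeys the variance bound", {
  for (seed in 1:10) {
    tr <- random_trace(seed)
    a <- magnitude(tr, "accel")
    sm <- as.numeric(smoothness(a, 100))
    expect_gte(sm, 0)
    expect_lte(sm, 1)
    miv <- movement_intensity_variation(accel_mat(tr))
    expect_lte(miv^2, mean(a^2) + 1e-12)
  }
})
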