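test_that("min-max scaling maps training columns onto [0,1] and inverts", {
  X <- cbind(a = c(2, 4, 6), b = c(-1, 0, 3))
  sc <- minmax_fit(X)
  Xs <- minmax_apply(sc, X)
  expect_equal(Xs[, "a"], c(0, 0.5, 1))
  expect_equal(range(Xs), c(0, 1))

  # out-of-range application extrapolates linearly
  expect_equal(unname(minmax_apply(sc, cbind(a = 8, b = 0))[1, "a"]), 1.5)

  # round trip through the bounds
  back <- sweep(sweep(Xs, 2, sc$max - sc$min, "*"), 2, sc$min, "+")
  expect_equal(back, X, tolerance = 1e-12)

  expect_error(minmax_fit(cbind(a = c(1, 1, 1), b = 1:3)), "a")
})

test_that("OLS recovers a noiseless line exactly", {
  X <- cbind(x = c(0, 1, 2, 3, 4))
  t <- 0.3 + 0.5 * X[, 1]
  m <- fit_capacity_model(X, t)
  expect_equal(m$intercept, 0.3, tolerance = 1e-10)
  expect_equal(unname(m$weights["x"]), 0.5, tolerance = 1e-10)
  expect_lt(m$sigma, 1e-10)
})

test_that("weights match a brute-force normal-equations oracle", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      X <- matrix(rnorm(40 * 3), 40, 3,
        dimnames = list(NULL, c("a", "b", "c"))
      )
      t <- 0.2 + X %*% c(0.5, -0.3, 0.1) + rnorm(40, 0, 0.1)
    })
    m <- fit_capacity_model(X, as.numeric(t))
    Xd <- cbind(1, X)
    beta <- solve(t(Xd) %*% Xd, t(Xd) %*% t)
    expect_equal(c(m$intercept, unname(m$weights)), as.numeric(beta),
      tolerance = 1e-8
    )
  }
})

test_that("rank-deficient designs fail naming collinear columns", {
  X <- cbind(a = 1:10, b = 2 * (1:10), c = rnorm(10))
  expect_error(fit_capacity_model(X, rnorm(10)), "collinear")
  expect_error(
    fit_capacity_model(cbind(a = 1:3), c(1, 2, NA)),
    "non-finite"
  )
})

test_that("the significance gate keeps real predictors and drops noise", {
  kept_signal <- 0
  kept_noise <- 0
  for (seed in 1:20) {
    withr::with_seed(seed, {
      X <- cbind(signal = rnorm(40), noise = rnorm(40))
      t <- 0.5 + 0.8 * X[, "signal"] + rnorm(40, 0, 0.2)
    })
    m <- fit_capacity_model(X, t)
    m2 <- select_significant(m, X, t, alpha = 0.05)
    kept_signal <- kept_signal + m2$retained[["signal"]]
    kept_noise <- kept_noise + m2$retained[["noise"]]
  }
  expect_gte(kept_signal, 18) # >= 90% of seeds
  expect_lte(kept_noise, 4)
})

test_that("all-noise designs collapse to a flagged intercept-only model", {
  withr::with_seed(3, {
    X <- cbind(a = rnorm(30), b = rnorm(30))
    t <- rep(0.4, 30) + rnorm(30, 0, 0.05)
  })
  m <- select_significant(fit_capacity_model(X, t), X, t)
  expect_true(m$intercept_only)
  expect_true(all(!m$retained))
  expect_equal(m$intercept, mean(t))
})

test_that("a fully significant model passes the gate unchanged", {
  withr::with_seed(4, {
    X <- cbind(a = rnorm(50), b = rnorm(50))
    t <- 0.2 + 0.9 * X[, 1] - 0.7 * X[, 2] + rnorm(50, 0, 0.05)
  })
  m <- fit_capacity_model(X, t)
  m2 <- select_significant(m, X, t)
  expect_identical(m2$weights, m$weights)
  expect_true(all(m2$retained))
})

test_that("evaluation metrics match closed-form hand computations", {
  e1 <- evaluate_predictions(c(0.2, 0.8), c(0.2, 0.8))
  expect_equal(e1$rmse, 0)
  expect_equal(e1$r, 1)

  e2 <- evaluate_predictions(c(0, 1), c(1, 0))
  expect_equal(e2$rmse, 1)
  expect_equal(e2$r, -1)

  for (seed in 1:5) {
    withr::with_seed(seed, {
      a <- runif(20)
      b <- runif(20)
    })
    e <- evaluate_predictions(a, b)
    expect_equal(e$rmse, sqrt(mean((a - b)^2)), tolerance = 1e-12)
    expect_equal(e$r, cor(a, b), tolerance = 1e-12)
  }
  expect_error(evaluate_predictions(1:3, 1:4), "equal length")
})

test_that("degenerate constant predictions are flagged, not silent NaN", {
  e <- evaluate_predictions(c(0.1, 0.5, 0.9), c(0.4, 0.4, 0.4))
  expect_true(e$degenerate)
  expect_true(is.na(e$r))
  expect_false(is.nan(e$rmse))
})

test_that("leave-one-session-out recovers generating weights without noise", {
  co <- simulate_cohort(
    n_subjects = 4L, n_weeks = 4L,
    task_list = default_task_list()[1:2, ],
    rating_noise_sd = 0, seed = 31
  )
  ev <- loso_cv(co$instances, "cards")
  expect_lt(ev$metrics$rmse, 1e-6)
  expect_gt(ev$metrics$r, 0.99)
  w <- coef_raw(ev$model)
  gen <- default_rating_weights("cards")
  nz <- names(gen[-1])[gen[-1] != 0]
  expect_lt(max(abs(w$weights[nz] - gen[nz])), 1e-6)
  expect_lt(abs(w$intercept - gen[[1]]), 1e-6)
  # only the truly contributing features survive the gate
  expect_true(all(ev$model$retained[nz]))
})

test_that("LOSO folds never leak: permuting instances changes nothing", {
  co <- simulate_cohort(
    n_subjects = 3L, n_weeks = 3L,
    task_list = default_task_list()[1:2, ],
    rating_noise_sd = 0.05, seed = 12
  )
  ev1 <- loso_cv(co$instances, "cards")
  withr::with_seed(1, idx <- sample(nrow(co$instances)))
  ev2 <- loso_cv(co$instances[idx, ], "cards")
  p1 <- dplyr::arrange(ev1$predictions, .data$subject_id, .data$week, .data$side)
  p2 <- dplyr::arrange(ev2$predictions, .data$subject_id, .data$week, .data$side)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("too few sessions is an explicit failure", {
  co <- simulate_cohort(
    n_subjects = 1L, n_weeks = 2L,
    task_list = default_task_list()[1:2, ],
    rating_noise_sd = 0, seed = 3
  )
  expect_error(loso_cv(co$instances, "cards"), "3 sessions")
})

test_that("paper-mode gating selects once on the full dataset and runs", {
  co <- simulate_cohort(
    n_subjects = 4L, n_weeks = 4L,
    task_list = default_task_list()[1:2, ],
    rating_noise_sd = 0.05, seed = 21
  )
  ev <- loso_cv(co$instances, "cards", paper_mode = TRUE)
  expect_true(is.finite(ev$metrics$rmse))
  expect_true(ev$paper_mode)
})

test_that("pooled task-independent features exclude TIME and DF", {
  co <- simulate_cohort(
    n_subjects = 2L, n_weeks = 2L,
    task_list = default_task_list()[1:2, ],
    rating_noise_sd = 0.05, seed = 6
  )
  po <- pooled_generalization(co$instances)
  expect_identical(
    names(po),
    c("subject_id", "week", "SM", "ARE", "RANG", "rating", "n_tasks")
  )
  expect_equal(nrow(po), 4L)
  # one instance per (subject, week) -> means equal that instance's values
  one <- co$instances[co$instances$side == "right", ]
  po1 <- pooled_generalization(one)
  i <- which(one$subject_id == po1$subject_id[1] & one$week == po1$week[1])
  expect_equal(po1$SM[1], one$features[[i]][["SM"]])
})

test_that("pooled feature clouds of mild and severe impairment separate", {
  mk <- function(level, seed) {
    simulate_cohort(
      n_subjects = 1L, n_weeks = 2L,
      task_list = default_task_list()[1:2, ],
      rating_noise_sd = 0, level_range = c(level, level),
      week_trend = 0, seed = seed
    )$instances
  }
  po_lo <- pooled_generalization(mk(0.1, 41))
  po_hi <- pooled_generalization(mk(0.9, 42))
  expect_gt(min(po_lo$SM), max(po_hi$SM))
  expect_gt(min(po_lo$ARE), max(po_hi$ARE))
  expect_gt(min(po_lo$RANG), max(po_hi$RANG))
})

test_that("tidy and glance methods expose the model and evaluation", {
  co <- simulate_cohort(
    n_subjects = 3L, n_weeks = 3L,
    task_list = default_task_list()[1:2, ],
    rating_noise_sd = 0.05, seed = 2
  )
  ev <- loso_cv(co$instances, "cards")
  td <- tidy(ev$model)
  expect_identical(
    names(td), c("term", "estimate", "std.error", "p.value", "retained")
  )
  expect_equal(nrow(td), 8L) # intercept + 7 features
  gl <- glance(ev)
  expect_true(all(c("rmse", "r", "n_sessions") %in% names(gl)))
  expect_s3_class(autoplot(ev), "ggplot")
})
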