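test_that("velocity estimator is exact for constant and linear motion", {
  const <- make_epoch(rep(0.2, 30), rep(-0.1, 30))
  v <- gaze_velocity(const)
  expect_equal(v$speed, rep(0, 30))

  t <- (0:29) / 256
  ramp <- make_epoch(3 * t, rep(0, 30))
  vr <- gaze_velocity(ramp)
  expect_equal(vr$speed[3:28], rep(3, 26), tolerance = 1e-10)

  expect_error(gaze_velocity(make_epoch(1:4 / 10, rep(0, 4))), "5-point")
})

test_that("velocity matches a brute-force evaluation of the 5-point formula", {
  withr::with_seed(31, {
    x <- rnorm(20); y <- rnorm(20)
  })
  ep <- make_epoch(x, y, sample_rate = 256)
  v <- gaze_velocity(ep)
  dt <- 1 / 256
  for (i in 3:18) {
    vx <- (x[i + 2] + x[i + 1] - x[i - 1] - x[i - 2]) / (6 * dt)
    vy <- (y[i + 2] + y[i + 1] - y[i - 1] - y[i - 2]) / (6 * dt)
    expect_equal(v$vx_left[i], vx)
    expect_equal(v$speed[i], sqrt(vx^2 + vy^2))
  }
  # edges are padded with the nearest interior value
  expect_equal(v$vx_left[1], v$vx_left[3])
  expect_equal(v$vx_left[20], v$vx_left[18])
})

test_that("microsaccade detection recovers an injected binocular event", {
  n <- 512
  withr::with_seed(5, {
    drift_x <- cumsum(rnorm(n, sd = 2e-4))
    drift_y <- cumsum(rnorm(n, sd = 2e-4))
  })
  jump <- c(rep(0, 250), 0.5 * seq(0, 1, length.out = 6), rep(0.5, 256))
  ep <- make_epoch(drift_x + jump, drift_y)
  ev <- detect_microsaccades(ep)
  expect_equal(nrow(ev), 2)  # one event per eye, both binocular
  expect_true(all(ev$binocular))
  expect_true(all(abs(ev$amplitude - 0.5) / 0.5 < 0.2))
  expect_true(all(ev$onset >= 245 & ev$offset <= 262))

  # smooth drift alone triggers nothing
  expect_equal(nrow(detect_microsaccades(make_epoch(drift_x, drift_y))), 0)
})

test_that("monocular events are excluded by the binocular criterion", {
  n <- 512
  withr::with_seed(6, {
    dx <- cumsum(rnorm(n, sd = 2e-4)); dy <- cumsum(rnorm(n, sd = 2e-4))
    dx2 <- cumsum(rnorm(n, sd = 2e-4)); dy2 <- cumsum(rnorm(n, sd = 2e-4))
  })
  jump <- c(rep(0, 250), 0.4 * seq(0, 1, length.out = 6), rep(0.4, 256))
  ep <- make_epoch(dx + jump, dy, x_right = dx2, y_right = dy2)
  expect_equal(nrow(detect_microsaccades(ep)), 0)
  all_ev <- detect_microsaccades(ep, binocular_only = FALSE)
  expect_true(any(all_ev$eye == "left" & !all_ev$binocular))
})

test_that("amplitude scaling scales detected amplitudes proportionally", {
  n <- 512
  withr::with_seed(7, {
    dx <- cumsum(rnorm(n, sd = 2e-4)); dy <- cumsum(rnorm(n, sd = 2e-4))
  })
  jump <- c(rep(0, 200), 0.3 * seq(0, 1, length.out = 6), rep(0.3, 306))
  e1 <- make_epoch(dx + jump, dy)
  e2 <- make_epoch(2 * (dx + jump), 2 * dy)
  a1 <- detect_microsaccades(e1)$amplitude
  a2 <- detect_microsaccades(e2)$amplitude
  expect_equal(a2, 2 * a1, tolerance = 1e-8)
})

test_that("a constant trace warns about zero velocity spread", {
  ep <- make_epoch(rep(0.1, 64), rep(0.1, 64))
  # both eyes warn; capture one per expectation
  expect_warning(
    expect_warning(ev <- detect_microsaccades(ep), "zero velocity spread"),
    "zero velocity spread")
  expect_equal(nrow(ev), 0)
})

test_that("distance and velocity filters keep and remove the right trials", {
  theta <- seq(0, 2 * pi, length.out = 64)
  near <- make_epoch(0.2 * cos(theta), 0.2 * sin(theta), orientation = 0)
  far <- make_epoch(1.5 * cos(theta), 1.5 * sin(theta), orientation = 45)
  rep_d <- filter_by_distance(list(near, far), 1.0, decode = FALSE)
  expect_equal(rep_d$kept_trials, 1L)
  expect_equal(rep_d$kept_fraction, 0.5)
  expect_equal(filter_by_distance(list(near, far), Inf,
                                  decode = FALSE)$kept_trials, c(1L, 2L))
  expect_equal(length(filter_by_distance(list(near, far), 0,
                                         decode = FALSE)$kept_trials), 0)
  expect_error(filter_by_distance(list(near), -1), "non-negative")

  t <- (0:63) / 256
  slow <- make_epoch(0.5 * t, rep(0, 64))   # 0.5 deg/s
  fast <- make_epoch(3 * t, rep(0, 64))     # 3 deg/s
  rep_v <- filter_by_velocity(list(slow, fast), 2, decode = FALSE)
  expect_equal(rep_v$kept_trials, 1L)
})

test_that("filters with threshold Inf reproduce the unfiltered decoding", {
  d <- small_design(n_runs = 2)
  ep <- preprocess_session(simulate_session(d, bias_model(seed = 14)))
  unfiltered <- crossval_decode(extract_features(ep), seed = 5)
  rep_inf <- filter_by_distance(ep, Inf, seed = 5)
  expect_equal(rep_inf$kept_fraction, 1)
  expect_identical(rep_inf$decoding$fold_accuracies,
                   unfiltered$fold_accuracies)
})

test_that("kept sets are nested across increasing thresholds", {
  d <- small_design(n_runs = 2)
  ep <- preprocess_session(simulate_session(
    d, bias_model("along_axis", bias_amplitude = 1.5, seed = 15)))
  for (ffun in list(filter_by_distance, filter_by_velocity)) {
    grid <- if (identical(ffun, filter_by_distance))
      c(0.25, 0.5, 1, 2, Inf) else c(10, 20, 50, 100, Inf)
    kept <- lapply(grid, function(th) ffun(ep, th, decode = FALSE)$kept_trials)
    for (i in seq_len(length(grid) - 1))
      expect_true(all(kept[[i]] %in% kept[[i + 1]]))
  }
})

test_that("distance filtering removes exactly the bias-injected trials", {
  d <- small_design(n_runs = 2)
  s <- simulate_session(d, bias_model("along_axis", bias_amplitude = 2.5,
                                      drift_sd = 0.05, microsaccade_rate = 0.3,
                                      microsaccade_amp_range = c(0.05, 0.15),
                                      seed = 16))
  ep <- preprocess_session(s)
  removed <- setdiff(seq_along(ep),
                     filter_by_distance(ep, 1.2, decode = FALSE)$kept_trials)
  expect_setequal(removed, which(s$ground_truth$biased))
})

test_that("threshold sweeps report the none condition and sentinels", {
  d <- small_design(n_runs = 2)
  cohort <- lapply(1:3, function(p) {
    list(active = preprocess_session(simulate_session(
           d, bias_model("along_axis", bias_amplitude = 1.5,
                         seed = 100 + p))),
         passive = preprocess_session(simulate_session(
           d, bias_model(seed = 200 + p))))
  })
  sw <- threshold_sweep(cohort, "distance", grid = c(0.01, 2), seed = 1)
  expect_equal(sw$comparison$threshold, c(0.01, 2, Inf))
  tight <- sw$accuracies[sw$accuracies$threshold == 0.01, ]
  expect_true(all(!tight$feasible))       # nearly everything removed
  expect_true(all(is.na(tight$accuracy))) # sentinel, never a number
  none <- sw$accuracies[sw$accuracies$threshold == Inf, ]
  expect_true(all(none$kept_fraction == 1))
  expect_error(threshold_sweep(cohort, "distance", grid = numeric(0)),
               "empty")
})
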