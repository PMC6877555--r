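test_that("blink repair substitutes the run median and keeps the mask", {
  x <- c(1, 2, NA, 4)
  rec <- make_recording(x, missing = is.na(x))
  out <- repair_blinks(rec)
  expect_equal(out$x_left[3], 2)  # median of {1, 2, 4}
  expect_identical(out$missing, is.na(x))

  clean <- make_recording(rnorm(20))
  expect_identical(repair_blinks(clean), clean)

  all_gone <- make_recording(rep(NA_real_, 10), missing = rep(TRUE, 10))
  expect_error(repair_blinks(all_gone), "median undefined")
})

test_that("low-pass filter has the designed frequency response", {
  t <- seq(0, 2, by = 1e-3)[-1]
  const <- make_recording(rep(0.7, length(t)))
  out <- lowpass(const)
  expect_equal(out$x_left, rep(0.7, length(t)), tolerance = 1e-6)

  # frequency response measured away from the edge transients
  hi <- make_recording(sin(2 * pi * 400 * t))
  out_hi <- lowpass(hi)
  i <- 200:1800
  rms <- function(v) sqrt(mean(v[i]^2))
  expect_lt(rms(out_hi$x_left) / rms(hi$x_left), 1 / 100)

  lo <- make_recording(sin(2 * pi * 1 * t))
  out_lo <- lowpass(lo)
  expect_equal(rms(out_lo$x_left) / rms(lo$x_left), 1, tolerance = 0.01)

  expect_error(lowpass(make_recording(rnorm(100)), cutoff_hz = 500),
               "Nyquist")
})

test_that("zero-phase filtering matches signal::filtfilt away from edges", {
  withr::with_seed(1, {
    x <- as.numeric(stats::filter(rnorm(5000, sd = 0.01), 0.98,
                                  method = "recursive"))
  })
  bf <- signal::butter(5, 100 / 500)
  ours <- lowpass(make_recording(x))$x_left
  ref <- signal::filtfilt(bf, x)
  i <- 200:4800
  expect_equal(ours[i], ref[i], tolerance = 1e-4)
})

test_that("downsampling lands on the 256 Hz grid and preserves shape", {
  t <- seq(0, 6999) / 1000
  rec <- make_recording(rep(1.5, 7000))
  out <- downsample(rec)
  expect_equal(length(out$x_left), 1792)
  expect_equal(out$sample_rate, 256)
  expect_equal(out$x_left, rep(1.5, 1792), tolerance = 1e-9)

  ramp <- make_recording(3 * t)
  out_r <- downsample(ramp)
  expect_equal(out_r$x_left, 3 * out_r$time_ms / 1000, tolerance = 1e-6)

  sine <- make_recording(sin(2 * pi * 30 * t))
  out_s <- downsample(lowpass(sine))
  expect_equal(out_s$x_left[100:1700],
               sin(2 * pi * 30 * out_s$time_ms / 1000)[100:1700],
               tolerance = 1e-3)

  expect_error(downsample(rec, target_hz = 2000), "exceeds")
  expect_identical(downsample(rec, target_hz = 1000), rec)
})

test_that("epoching cuts one labelled 1792-sample epoch per trial onset", {
  d <- small_design(n_runs = 1)
  s <- simulate_session(d, bias_model(seed = 3))
  rec <- downsample(lowpass(repair_blinks(s$runs[[1]])))
  ep <- epoch_trials(rec)
  expect_length(ep, d$trials_per_run)
  expect_true(all(vapply(ep, function(e) nrow(e$data), 1) == 1792))
  expect_equal(vapply(ep, function(e) e$orientation, 1),
               s$ground_truth$orientation)
  expect_equal(vapply(ep, function(e) e$run, 1L), rep(1L, 8))

  # truncated recording: last trial extends past the end
  short <- rec
  keep <- seq_len(length(rec$time_ms) - 3000)
  for (ch in c("time_ms", "x_left", "y_left", "x_right", "y_right",
               "pupil_left", "pupil_right", "missing"))
    short[[ch]] <- short[[ch]][keep]
  expect_error(epoch_trials(short), "beyond the recording")
})

test_that("run-median centering removes per-run offsets and is idempotent", {
  e1 <- make_epoch(rnorm(100) + 0.5, rnorm(100) - 0.2, run = 1)
  e2 <- make_epoch(rnorm(100) + 0.5, rnorm(100) - 0.2, run = 1)
  e3 <- make_epoch(rnorm(100) - 1.0, rnorm(100), run = 2)
  cen <- center_runs(list(e1, e2, e3))
  run1 <- rbind(cen[[1]]$data, cen[[2]]$data)
  expect_equal(unname(apply(run1, 2, median)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(cen[[3]]$data, 2, median)), rep(0, 6),
               tolerance = 1e-12)
  again <- center_runs(cen)
  expect_equal(again, cen, tolerance = 1e-12)
})

test_that("the full chain yields one centred epoch per designed trial", {
  d <- small_design(n_runs = 2)
  s <- simulate_session(d, bias_model(seed = 12))
  ep <- preprocess_session(s)
  expect_length(ep, total_trials(d))
  expect_true(all(vapply(ep, function(e) nrow(e$data), 1) == 1792))
  stacked <- do.call(rbind, lapply(ep[1:8], function(e) e$data))
  expect_equal(unname(apply(stacked, 2, median)), rep(0, 6), tolerance = 1e-9)
})
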