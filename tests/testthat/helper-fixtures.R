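# Shared fixtures: everything is generated in code at test time.

# A reduced design for fast unit tests: 4 orientations, 8 trials/run.
small_design <- function(session_type = "passive", n_runs = 2,
                         orientations = c(0, 45, 90, 135), ...) {
  make_design(session_type, n_runs = n_runs, orientations = orientations, ...)
}

# Build a trial_epoch directly from channel vectors (defaults: both eyes
# follow x/y, pupils constant).
make_epoch <- function(x, y, sample_rate = 256, orientation = 0, run = 1L,
                       task = FALSE, x_right = x, y_right = y) {
  n <- length(x)
  dat <- cbind(x_left = x, y_left = y, x_right = x_right, y_right = y_right,
               pupil_left = rep(1000, n), pupil_right = rep(1000, n))
  structure(list(orientation = orientation, task = task, run = as.integer(run),
                 sample_rate = sample_rate, data = dat),
            class = "trial_epoch")
}

# A minimal valid gaze_recording wrapping one channel pattern.
make_recording <- function(x, sample_rate = 1000, missing = rep(FALSE, length(x)),
                           y = x, pupil = rep(1000, length(x)), events = NULL) {
  n <- length(x)
  if (is.null(events))
    events <- data.frame(time_ms = c(0, (n - 1) * 1000 / sample_rate),
                         kind = c("run_start", "run_end"),
                         orientation_deg = NA_real_, task_flag = NA)
  gaze_recording(sample_rate = sample_rate,
                 time_ms = (seq_len(n) - 1) * 1000 / sample_rate,
                 x_left = x, y_left = y, x_right = x, y_right = y,
                 pupil_left = pupil, pupil_right = pupil,
                 missing = missing, events = events)
}

# Synthetic feature matrix: k classes, n_per_class trials each, d features,
# class means separated by `sep` in units of the noise SD.
make_features <- function(n_per_class = 24, k = 8, d = 12, sep = 0, seed = 1) {
  withr::with_seed(seed, {
    n <- n_per_class * k
    labels <- rep(seq_len(k), each = n_per_class)
    mu <- matrix(rnorm(k * d), k, d) * sep
    x <- matrix(rnorm(n * d), n, d) + mu[labels, ]
    colnames(x) <- c(paste0("mean_", gazedecode:::ALL_CHANNELS),
                     paste0("sd_", gazedecode:::ALL_CHANNELS))[seq_len(d)]
    structure(list(x = x,
                   orientation = (labels - 1) * (180 / k),
                   run = rep(1L, n), session_type = "passive"),
              class = "feature_matrix")
  })
}
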