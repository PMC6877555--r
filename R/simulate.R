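#' Fixational noise and gaze-bias model for synthetic sessions
#'
#' Parameters of the synthetic gaze generator. Fixational noise comprises a
#' mean-reverting drift process, microsaccades with a linear
#' amplitude--peak-velocity relation (main sequence), and blinks recorded as
#' missing-sample spans. Optionally, orientation-dependent gaze bias is
#' injected as brief out-and-back excursions along the stimulus axis (or the
#' orthogonal axis), confined to stimulus-on periods, mimicking the
#' stimulus-directed eye movements that confound decoding.
#'
#' @param mode `"none"` (traces statistically identical across orientations),
#'   `"along_axis"` (excursions along the grating orientation, treated mod
#'   180 degrees with random sign per excursion), or `"orthogonal_axis"`.
#' @param bias_amplitude excursion extent in degrees of visual angle.
#' @param bias_trial_prob probability that a trial is "tracked", i.e.
#'   contains stimulus-directed excursions at all; systematic eye movements
#'   occur on a subset of trials, leaving enough clean trials for filtered
#'   re-analysis.
#' @param excursion_rate mean bias excursions per second of trial time,
#'   within tracked trials.
#' @param drift_sd drift innovation scale, degrees per square-root second;
#'   the default gives a stationary fixational scatter of roughly 0.1 degree.
#' @param microsaccade_rate microsaccades per second.
#' @param microsaccade_amp_range amplitude range (degrees), sampled uniformly.
#' @param blink_rate blinks per minute.
#' @param blink_duration_ms blink duration in milliseconds.
#' @param pupil_baseline,pupil_noise_sd pupil level and white-noise scale,
#'   arbitrary tracker units.
#' @param seed integer seed; the generator is fully deterministic given the
#'   seed and design.
#'
#' @return An object of class `bias_model`.
#' @export
bias_model <- function(mode = c("none", "along_axis", "orthogonal_axis"),
                       bias_amplitude = 0,
                       bias_trial_prob = 0.3,
                       excursion_rate = 1.0,
                       drift_sd = 0.2,
                       microsaccade_rate = 1.2,
                       microsaccade_amp_range = c(0.05, 0.25),
                       blink_rate = 3,
                       blink_duration_ms = 150,
                       pupil_baseline = 1000,
                       pupil_noise_sd = 5,
                       seed = 1L) {
  mode <- match.arg(mode)
  if (bias_amplitude < 0) stop("bias_amplitude must be >= 0", call. = FALSE)
  stopifnot(length(microsaccade_amp_range) == 2,
            microsaccade_amp_range[1] > 0,
            diff(microsaccade_amp_range) >= 0,
            drift_sd >= 0, microsaccade_rate >= 0, blink_rate >= 0,
            excursion_rate >= 0, blink_duration_ms > 0,
            bias_trial_prob >= 0, bias_trial_prob <= 1)
  structure(list(mode = mode, bias_amplitude = bias_amplitude,
                 bias_trial_prob = bias_trial_prob,
                 excursion_rate = excursion_rate, drift_sd = drift_sd,
                 microsaccade_rate = microsaccade_rate,
                 microsaccade_amp_range = microsaccade_amp_range,
                 blink_rate = blink_rate,
                 blink_duration_ms = blink_duration_ms,
                 pupil_baseline = pupil_baseline,
                 pupil_noise_sd = pupil_noise_sd,
                 seed = as.integer(seed)),
            class = "bias_model")
}

#' @export
print.bias_model <- function(x, ...) {
  cat(sprintf("<bias_model: mode=%s amplitude=%g deg, seed=%d>\n",
              x$mode, x$bias_amplitude, x$seed))
  invisible(x)
}

# Mean-reverting (Ornstein-Uhlenbeck) random walk, Euler steps of dt seconds.
ou_process <- function(n, dt, tau, innov_sd) {
  if (innov_sd == 0) return(numeric(n))
  eps <- rnorm(n, sd = innov_sd * sqrt(dt))
  as.numeric(stats::filter(eps, 1 - dt / tau, method = "recursive"))
}

# Main-sequence constants: peak velocity (deg/s) = MS_V0 + MS_SLOPE * amplitude.
MS_V0 <- 20
MS_SLOPE <- 60
# Excursion direction follows the preferred sign with this probability.
SIGN_CONSISTENCY <- 0.9
# Microsaccades re-center gaze once the accumulated offset exceeds this (deg).
RECENTER_RADIUS <- 0.15

# Cumulative displacement profile of a raised-cosine velocity waveform,
# evaluated at n_samp points spanning the movement; total displacement 1.
raised_cosine_profile <- function(n_samp) {
  t <- seq(0, 1, length.out = n_samp)
  t - sin(2 * pi * t) / (2 * pi)
}

#' Simulate one synthetic session
#'
#' Generates a complete session of binocular gaze recordings with the given
#' design: per-run sample streams at the design sampling rate covering the
#' pre-trial fixation period, all trials with inter-trial intervals, and the
#' post-trial fixation period. Gaze channels are in degrees of visual angle
#' relative to fixation (+x right, +y up), binocularly correlated with small
#' vergence noise; pupil channels are in arbitrary units. Blinks appear as
#' missing-sample spans (channels `NA`, mask set); blink spans never cover a
#' trial-onset sample so epoching stays well defined. Every trial onset is
#' annotated with its orientation and task flag. With `mode != "none"`,
#' orientation-dependent excursions are injected only during stimulus-on
#' periods. The output is bit-identical for identical seeds.
#'
#' @param design an [make_design()] object.
#' @param bias a [bias_model()].
#' @return An object of class `raw_session`: list with elements `design`,
#'   `runs` (list of `gaze_recording`), and `ground_truth` (per-trial
#'   data.frame: run, trial, orientation, task, biased, onset_ms).
#' @export
#' @examples
#' d <- make_design("passive", n_runs = 1, orientations = c(0, 45, 90, 135))
#' s <- simulate_session(d, bias_model(seed = 42))
#' nrow(s$ground_truth)  # 8
simulate_session <- function(design, bias = bias_model()) {
  validate_design(design)
  stopifnot(inherits(bias, "bias_model"))
  withr::with_seed(bias$seed, {
    # each participant/session has an idiosyncratic preferred excursion
    # direction per orientation (which end of the axis), giving the
    # asymmetric per-orientation gaze lobes seen in biased participants
    pref_sign <- stats::setNames(
      sample(c(-1, 1), length(design$orientations), replace = TRUE),
      as.character(design$orientations))
    runs <- vector("list", design$n_runs)
    gt <- vector("list", design$n_runs)
    for (r in seq_len(design$n_runs)) {
      sim <- simulate_run(design, bias, r, pref_sign)
      runs[[r]] <- sim$recording
      gt[[r]] <- sim$ground_truth
    }
    structure(list(design = design, runs = runs,
                   ground_truth = do.call(rbind, gt)),
              class = "raw_session")
  })
}

simulate_run <- function(design, bias, run_index, pref_sign = NULL) {
  fs <- design$sample_rate
  dt <- 1 / fs
  tpr <- design$trials_per_run
  run_dur <- design$fixation_pre + tpr * design$trial_duration +
    (tpr - 1) * design$inter_trial_interval + design$fixation_post
  n <- round(run_dur * fs)
  step_ms <- 1000 / fs
  time_ms <- (seq_len(n) - 1) * step_ms

  onsets_s <- design$fixation_pre +
    (seq_len(tpr) - 1) * (design$trial_duration + design$inter_trial_interval)
  onset_ms <- onsets_s * 1000
  onset_idx <- round(onset_ms / step_ms) + 1L

  orientation <- sample(rep(design$orientations, 2L))

  task <- rep(FALSE, tpr)
  if (design$session_type == "active") {
    plan <- design$task_plan[design$task_plan$run == run_index, , drop = FALSE]
    for (i in seq_len(nrow(plan))) {
      slots <- which(orientation == plan$orientation[i] & !task)
      task[slots[min(plan$occurrence[i], length(slots))]] <- TRUE
    }
  }

  # --- common binocular gaze signal ------------------------------------
  gx <- ou_process(n, dt, tau = 0.7, innov_sd = bias$drift_sd)
  gy <- ou_process(n, dt, tau = 0.7, innov_sd = bias$drift_sd)

  ms <- make_microsaccades(n, fs, bias)
  gx <- gx + ms$x
  gy <- gy + ms$y

  biased_trial <- rep(FALSE, tpr)
  if (bias$mode != "none") {
    # run the excursion generator even at amplitude 0, so that sessions
    # differing only in bias_amplitude share every other random draw
    # (paired/common-random-number comparisons across amplitudes)
    exc <- inject_excursions(n, fs, design, bias, onset_idx, orientation,
                             pref_sign)
    gx <- gx + exc$x
    gy <- gy + exc$y
    biased_trial <- exc$biased_trial
  }

  verg_sd <- 0.05  # deg/sqrt(s); ~0.03 deg stationary per-eye disparity noise
  x_left <- gx + ou_process(n, dt, 0.5, verg_sd)
  y_left <- gy + ou_process(n, dt, 0.5, verg_sd)
  x_right <- gx + ou_process(n, dt, 0.5, verg_sd)
  y_right <- gy + ou_process(n, dt, 0.5, verg_sd)

  # --- pupil ------------------------------------------------------------
  slow <- bias$pupil_baseline *
    (1 + ou_process(n, dt, tau = 5, innov_sd = 0.01))
  pupil_left <- slow + rnorm(n, sd = bias$pupil_noise_sd)
  pupil_right <- slow + rnorm(n, sd = bias$pupil_noise_sd)

  # --- blinks (never covering a trial-onset sample) ---------------------
  missing <- rep(FALSE, n)
  n_blinks <- rpois(1, bias$blink_rate / 60 * run_dur)
  blink_len <- max(1L, round(bias$blink_duration_ms / step_ms))
  if (n_blinks > 0) {
    starts <- sort(sample.int(n - blink_len, n_blinks))
    for (s in starts) {
      span <- s:(s + blink_len - 1L)
      if (any(onset_idx %in% span)) next
      missing[span] <- TRUE
    }
  }
  x_left[missing] <- NA_real_
  y_left[missing] <- NA_real_
  x_right[missing] <- NA_real_
  y_right[missing] <- NA_real_
  pupil_left[missing] <- NA_real_
  pupil_right[missing] <- NA_real_

  events <- data.frame(
    time_ms = c(0, onset_ms, time_ms[n]),
    kind = c("run_start", rep("trial_onset", tpr), "run_end"),
    orientation_deg = c(NA, orientation, NA),
    task_flag = c(NA, task, NA)
  )

  rec <- gaze_recording(sample_rate = fs, time_ms = time_ms,
                        x_left = x_left, y_left = y_left,
                        x_right = x_right, y_right = y_right,
                        pupil_left = pupil_left, pupil_right = pupil_right,
                        missing = missing, events = events,
                        run_index = run_index,
                        orientations = design$orientations)
  list(recording = rec,
       ground_truth = data.frame(run = run_index, trial = seq_len(tpr),
                                 orientation = orientation, task = task,
                                 biased = biased_trial, onset_ms = onset_ms))
}

# Microsaccade displacement field for one run: Poisson event times, uniform
# direction (re-centering when the accumulated offset grows), amplitude
# uniform in range, duration from the linear main sequence with a
# raised-cosine velocity profile. Built as per-sample displacement
# increments and integrated once, so the permanent post-event offsets come
# out of the cumulative sum instead of O(n) tail updates per event.
make_microsaccades <- function(n, fs, bias) {
  dur_s <- n / fs
  k <- rpois(1, bias$microsaccade_rate * dur_s)
  if (k == 0) return(list(x = numeric(n), y = numeric(n)))
  t0 <- sort(sample.int(n, k))
  amp <- runif(k, bias$microsaccade_amp_range[1], bias$microsaccade_amp_range[2])
  dx <- numeric(n); dy <- numeric(n)
  sx <- 0; sy <- 0  # accumulated offset, used to keep gaze near fixation
  for (i in seq_len(k)) {
    if (sqrt(sx^2 + sy^2) > RECENTER_RADIUS) {
      ang <- atan2(-sy, -sx) + rnorm(1, sd = pi / 6)
    } else {
      ang <- runif(1, 0, 2 * pi)
    }
    a <- amp[i]
    v_peak <- MS_V0 + MS_SLOPE * a
    len <- max(4L, round(2 * a / v_peak * fs))
    idx <- t0[i]:min(n, t0[i] + len - 1L)
    step <- a * diff(c(0, raised_cosine_profile(len)))[seq_along(idx)]
    ux <- cos(ang); uy <- sin(ang)
    dx[idx] <- dx[idx] + ux * step
    dy[idx] <- dy[idx] + uy * step
    sx <- sx + ux * a; sy <- sy + uy * a
  }
  list(x = cumsum(dx), y = cumsum(dy))
}

# Orientation-dependent excursions: on a "tracked" subset of trials
# (probability bias_trial_prob), saccadic out-and-back movements along the
# trial's orientation axis (mod 180) or its orthogonal. Each excursion is an
# outward saccade with main-sequence peak velocity, a ~150 ms hold at the
# excursion extent, and a return saccade, so both position- and
# velocity-based trial filters can catch it. Excursion direction follows the
# session's per-orientation preferred sign with probability SIGN_CONSISTENCY
# (flipping otherwise), giving the direction-consistent per-orientation
# lobes characteristic of biased participants. Excursions start at
# stimulus-on period onsets. Built as increments and integrated once.
inject_excursions <- function(n, fs, design, bias, onset_idx, orientation,
                              pref_sign) {
  dx <- numeric(n); dy <- numeric(n)
  tpr <- design$trials_per_run
  biased_trial <- rep(FALSE, tpr)
  A <- bias$bias_amplitude
  v_peak <- MS_V0 + MS_SLOPE * A
  sac_len <- max(4L, round(2 * A / v_peak * fs))
  inject <- A > 0
  hold_len <- round(0.25 * fs)
  sac_step <- A * diff(c(0, raised_cosine_profile(sac_len)))
  on_starts_s <- seq(0, design$trial_duration - design$on_ms / 1000,
                     by = 1 / design$presentation_rate)
  tracked <- runif(tpr) < bias$bias_trial_prob
  for (tr in seq_len(tpr)) {
    if (!tracked[tr]) next
    k <- rpois(1, bias$excursion_rate * design$trial_duration)
    if (k == 0) next
    biased_trial[tr] <- inject
    theta <- orientation[tr] * pi / 180
    if (bias$mode == "orthogonal_axis") theta <- theta + pi / 2
    starts <- sample(on_starts_s, k, replace = TRUE)
    base_sign <- if (is.null(pref_sign)) 1
                 else pref_sign[[as.character(orientation[tr])]]
    sgn <- base_sign * ifelse(runif(k) < SIGN_CONSISTENCY, 1, -1)
    if (!inject) next
    for (i in seq_len(k)) {
      i_out <- onset_idx[tr] + round(starts[i] * fs)
      i_back <- i_out + sac_len + hold_len
      ux <- sgn[i] * cos(theta); uy <- sgn[i] * sin(theta)
      span_out <- i_out:min(n, i_out + sac_len - 1L)
      dx[span_out] <- dx[span_out] + ux * sac_step[seq_along(span_out)]
      dy[span_out] <- dy[span_out] + uy * sac_step[seq_along(span_out)]
      if (i_back <= n) {
        span_back <- i_back:min(n, i_back + sac_len - 1L)
        dx[span_back] <- dx[span_back] - ux * sac_step[seq_along(span_back)]
        dy[span_back] <- dy[span_back] - uy * sac_step[seq_along(span_back)]
      }
    }
  }
  list(x = cumsum(dx), y = cumsum(dy), biased_trial = biased_trial)
}

#' Per-trial ground-truth label table of a synthetic session
#'
#' @param session a `raw_session` from [simulate_session()].
#' @param path optional file path; when given the table is written as
#'   tab-separated text.
#' @return The ground-truth data.frame (one row per trial: run, trial,
#'   orientation, task flag, injected-bias flag, onset time).
#' @export
write_ground_truth <- function(session, path = NULL) {
  stopifnot(inherits(session, "raw_session"))
  gt <- session$ground_truth
  if (!is.null(path))
    utils::write.table(gt, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(gt)
}

#' @export
print.raw_session <- function(x, ...) {
  cat(sprintf("<raw_session: %s, %d runs, %d trials, %d biased>\n",
              x$design$session_type, length(x$runs), nrow(x$ground_truth),
              sum(x$ground_truth$biased)))
  invisible(x)
}
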