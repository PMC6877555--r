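#' Replace blink samples by run medians
#'
#' Every masked (missing) sample of every channel is replaced by that
#' channel's median over the run's unmasked samples, i.e. by the fixation
#' point for centred gaze. The mask is retained for provenance.
#'
#' @param recording a `gaze_recording`.
#' @return The recording with missing samples filled in.
#' @export
repair_blinks <- function(recording) {
  validate_recording(recording)
  if (!any(recording$missing)) return(recording)
  idx <- which(recording$missing)
  for (ch in ALL_CHANNELS) {
    good <- recording[[ch]][!recording$missing]
    if (all(is.na(good)) || length(good) == 0)
      stop("channel ", ch, " has no unmasked samples; median undefined",
           call. = FALSE)
    recording[[ch]][idx] <- median(good, na.rm = TRUE)
  }
  recording
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass (default order 5, cutoff 100 Hz) to every
#' channel, forward and backward so the net phase is zero and saccade timing
#' is preserved. DC is passed unchanged. The effective magnitude response is
#' the square of the single-pass response.
#'
#' @param recording a `gaze_recording` (blink-repaired; `NA`-free channels).
#' @param order filter order.
#' @param cutoff_hz cutoff frequency, Hz; must be below Nyquist.
#' @return The filtered recording.
#' @export
lowpass <- function(recording, order = 5, cutoff_hz = 100) {
  validate_recording(recording)
  nyq <- recording$sample_rate / 2
  if (cutoff_hz >= nyq)
    stop(sprintf("cutoff %g Hz is not below the Nyquist frequency %g Hz",
                 cutoff_hz, nyq), call. = FALSE)
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  for (ch in ALL_CHANNELS) {
    x <- recording[[ch]]
    if (anyNA(x))
      stop("channel ", ch, " contains NA; run repair_blinks() first",
           call. = FALSE)
    recording[[ch]] <- filtfilt_iir(bf$b, bf$a, x)
  }
  recording
}

#' Downsample a recording
#'
#' Resamples every channel onto a uniform grid at the target rate (default
#' 256 Hz) by cubic-spline interpolation. The recording must already be
#' low-pass filtered below the target Nyquist frequency ([lowpass()] is the
#' anti-alias stage); on such band-limited data the interpolation is accurate
#' to a fraction of a percent. Event times are unchanged (milliseconds); the
#' missing mask is carried over by nearest-sample lookup.
#'
#' @param recording a `gaze_recording`.
#' @param target_hz new sampling rate; must not exceed the current one.
#' @return The resampled recording.
#' @export
downsample <- function(recording, target_hz = 256) {
  validate_recording(recording)
  fs <- recording$sample_rate
  if (target_hz > fs)
    stop(sprintf("target rate %g Hz exceeds source rate %g Hz",
                 target_hz, fs), call. = FALSE)
  if (target_hz == fs) return(recording)
  t_in <- recording$time_ms
  step <- 1000 / target_hz
  n_out <- floor((t_in[length(t_in)] - t_in[1]) / step) + 1
  t_out <- t_in[1] + (seq_len(n_out) - 1) * step
  for (ch in ALL_CHANNELS)
    recording[[ch]] <- spline(t_in, recording[[ch]], xout = t_out)$y
  nearest <- pmin(length(t_in),
                  pmax(1L, round((t_out - t_in[1]) / (1000 / fs)) + 1L))
  recording$missing <- recording$missing[nearest]
  recording$time_ms <- t_out
  recording$sample_rate <- target_hz
  validate_recording(recording)
}

#' Slice a recording into trial epochs
#'
#' Cuts one epoch per `trial_onset` event, locked to the onset of the first
#' stimulus presentation, of `trial_duration` seconds (1792 samples for 7 s
#' at 256 Hz). Each epoch carries its orientation label, task flag, and run
#' index.
#'
#' @param recording a preprocessed `gaze_recording`.
#' @param trial_duration epoch length in seconds.
#' @return A list of `trial_epoch` objects; each holds a samples-by-6 channel
#'   matrix (`x_left, y_left, x_right, y_right, pupil_left, pupil_right`).
#' @export
epoch_trials <- function(recording, trial_duration = 7) {
  validate_recording(recording)
  fs <- recording$sample_rate
  n_epoch <- round(trial_duration * fs)
  onsets <- recording$events[recording$events$kind == "trial_onset", ]
  n <- length(recording$time_ms)
  out <- vector("list", nrow(onsets))
  for (i in seq_len(nrow(onsets))) {
    start <- round((onsets$time_ms[i] - recording$time_ms[1]) * fs / 1000) + 1L
    if (start < 1 || start + n_epoch - 1L > n)
      stop(sprintf(
        "trial %d (onset %g ms) extends beyond the recording (%d samples)",
        i, onsets$time_ms[i], n), call. = FALSE)
    idx <- start:(start + n_epoch - 1L)
    dat <- vapply(ALL_CHANNELS, function(ch) recording[[ch]][idx],
                  numeric(n_epoch))
    out[[i]] <- structure(list(
      orientation = onsets$orientation_deg[i],
      task = isTRUE(onsets$task_flag[i]),
      run = recording$run_index,
      sample_rate = fs,
      data = dat), class = "trial_epoch")
  }
  out
}

#' @export
print.trial_epoch <- function(x, ...) {
  cat(sprintf(
    "<trial_epoch: run %d, orientation %g deg%s, %d samples at %g Hz>\n",
    x$run, x$orientation, if (x$task) " (task)" else "",
    nrow(x$data), x$sample_rate))
  invisible(x)
}

#' Center epochs by run medians
#'
#' For each run and channel, subtracts the median over all samples of that
#' run's epochs, expressing gaze relative to the fixation point and removing
#' within-run biases. Pupil channels are included. Idempotent up to numerical
#' tolerance.
#'
#' @param epochs list of `trial_epoch` objects with run indices populated.
#' @return The centred epochs.
#' @export
center_runs <- function(epochs) {
  stopifnot(length(epochs) > 0)
  runs <- vapply(epochs, function(e) e$run, integer(1))
  for (r in unique(runs)) {
    in_run <- which(runs == r)
    stacked <- do.call(rbind, lapply(epochs[in_run], function(e) e$data))
    med <- apply(stacked, 2, median)
    for (i in in_run)
      epochs[[i]]$data <- sweep(epochs[[i]]$data, 2, med)
  }
  epochs
}

#' Run the full preprocessing chain on a session
#'
#' Applies, per run and in this fixed order: blink repair, zero-phase
#' Butterworth low-pass, downsampling, trial epoching; then run-median
#' centering across the pooled epochs.
#'
#' @param session a `raw_session` (or a plain list of `gaze_recording` runs).
#' @param order,cutoff_hz low-pass settings, see [lowpass()].
#' @param target_hz target sampling rate, see [downsample()].
#' @param trial_duration epoch length in seconds.
#' @return A list of centred `trial_epoch` objects spanning the session.
#' @export
#' @examples
#' d <- make_design("passive", n_runs = 1, orientations = c(0, 90))
#' s <- simulate_session(d, bias_model(seed = 7))
#' ep <- preprocess_session(s)
#' length(ep)  # 4 trials
preprocess_session <- function(session, order = 5, cutoff_hz = 100,
                               target_hz = 256, trial_duration = NULL) {
  runs <- if (inherits(session, "raw_session")) session$runs else session
  if (is.null(trial_duration))
    trial_duration <- if (inherits(session, "raw_session"))
      session$design$trial_duration else 7
  epochs <- list()
  for (rec in runs) {
    rec <- repair_blinks(rec)
    rec <- lowpass(rec, order = order, cutoff_hz = cutoff_hz)
    rec <- downsample(rec, target_hz = target_hz)
    epochs <- c(epochs, epoch_trials(rec, trial_duration = trial_duration))
  }
  center_runs(epochs)
}
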