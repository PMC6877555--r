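#' Per-trial summary features
#'
#' Computes, for every epoch, the mean and standard deviation of each of the
#' six recorded channels (binocular Cartesian gaze position and pupil
#' dilation), yielding 12 features per trial. Task trials are excluded by
#' default, since their perturbation may itself evoke eye movements. The SD
#' uses the population (divide-by-n) convention; at 1792 samples per epoch
#' the difference from the sample convention is negligible, but the choice is
#' fixed for reproducibility.
#'
#' @param epochs list of preprocessed `trial_epoch` objects.
#' @param drop_task_trials drop task-flagged trials?
#' @param session_type optional label stored with the matrix.
#' @return An object of class `feature_matrix`: list with `x` (trials x 12
#'   numeric matrix), `orientation`, `run`, `session_type`.
#' @export
extract_features <- function(epochs, drop_task_trials = TRUE,
                             session_type = NULL) {
  if (length(epochs) == 0) stop("no epochs to extract features from",
                                call. = FALSE)
  if (drop_task_trials)
    epochs <- Filter(function(e) !isTRUE(e$task), epochs)
  if (length(epochs) == 0)
    stop("no epochs left after dropping task trials", call. = FALSE)
  feat <- t(vapply(epochs, function(e) {
    m <- colMeans(e$data)
    v <- colMeans(e$data^2) - m^2
    c(m, sqrt(pmax(v, 0)))
  }, numeric(2 * length(ALL_CHANNELS))))
  colnames(feat) <- c(paste0("mean_", ALL_CHANNELS),
                      paste0("sd_", ALL_CHANNELS))
  structure(list(
    x = feat,
    orientation = vapply(epochs, function(e) e$orientation, numeric(1)),
    run = vapply(epochs, function(e) e$run, integer(1)),
    session_type = session_type), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d trials x %d features, %d orientations>\n",
              nrow(x$x), ncol(x$x), length(unique(x$orientation))))
  invisible(x)
}

#' Eye-movement amplitude of a trial
#'
#' Mean over samples of the radial distance of the binocular-average gaze
#' position from fixation, in degrees of visual angle. Epochs should be
#' centred ([center_runs()]) so that zero is the fixation point.
#'
#' @param epoch a `trial_epoch`.
#' @return Amplitude in degrees.
#' @export
trial_amplitude <- function(epoch) {
  bx <- (epoch$data[, "x_left"] + epoch$data[, "x_right"]) / 2
  by <- (epoch$data[, "y_left"] + epoch$data[, "y_right"]) / 2
  mean(sqrt(bx^2 + by^2))
}

#' Participant-level eye-movement amplitude
#'
#' Mean over trials of [trial_amplitude()].
#'
#' @param epochs list of `trial_epoch` objects.
#' @return Amplitude in degrees.
#' @export
session_amplitude <- function(epochs) {
  stopifnot(length(epochs) > 0)
  mean(vapply(epochs, trial_amplitude, numeric(1)))
}
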