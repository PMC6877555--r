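#' Construct a gaze recording
#'
#' Container for one run of binocular eye-tracking samples. Gaze channels are
#' degrees of visual angle relative to fixation, pupil channels arbitrary
#' units. Missing samples (blinks) are `NA` in the channels with the
#' corresponding mask entry set. Events annotate the run: a `run_start`, one
#' `trial_onset` per trial (carrying orientation and task flag), and a
#' `run_end`.
#'
#' @param sample_rate sampling rate, Hz.
#' @param time_ms sample timestamps in milliseconds, uniform with step
#'   `1000 / sample_rate`.
#' @param x_left,y_left,x_right,y_right gaze channels, degrees.
#' @param pupil_left,pupil_right pupil channels, arbitrary units.
#' @param missing logical mask of missing samples.
#' @param events data.frame with columns `time_ms`, `kind`,
#'   `orientation_deg`, `task_flag`.
#' @param run_index run number within the session.
#' @param orientations optional vector of valid orientations; when present,
#'   every trial onset's orientation is checked for membership.
#' @return An object of class `gaze_recording`.
#' @export
gaze_recording <- function(sample_rate, time_ms, x_left, y_left, x_right,
                           y_right, pupil_left, pupil_right, missing, events,
                           run_index = 1L, orientations = NULL) {
  rec <- structure(list(sample_rate = sample_rate,
                        time_ms = as.numeric(time_ms),
                        x_left = as.numeric(x_left),
                        y_left = as.numeric(y_left),
                        x_right = as.numeric(x_right),
                        y_right = as.numeric(y_right),
                        pupil_left = as.numeric(pupil_left),
                        pupil_right = as.numeric(pupil_right),
                        missing = as.logical(missing),
                        events = events,
                        run_index = as.integer(run_index),
                        orientations = orientations),
                   class = "gaze_recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  n <- length(rec$time_ms)
  fail <- function(msg) stop("invalid recording: ", msg, call. = FALSE)
  for (ch in c(ALL_CHANNELS, "missing"))
    if (length(rec[[ch]]) != n) fail(paste(ch, "length differs from time_ms"))
  if (n > 1) {
    step <- 1000 / rec$sample_rate
    d <- diff(rec$time_ms)
    if (any(d <= 0)) fail("timestamps not strictly increasing")
    if (max(abs(d - step)) > 1e-6 * step)
      fail(sprintf("timestamps not uniform at %g ms steps", step))
  }
  ev <- rec$events
  if (!all(c("time_ms", "kind", "orientation_deg", "task_flag") %in% names(ev)))
    fail("events must have columns time_ms, kind, orientation_deg, task_flag")
  bad <- setdiff(unique(ev$kind), c("run_start", "trial_onset", "run_end"))
  if (length(bad)) fail(paste("unknown event kind:", bad[1]))
  onsets <- ev[ev$kind == "trial_onset", ]
  if (any(is.na(onsets$orientation_deg)))
    fail("trial_onset events must carry an orientation")
  if (!is.null(rec$orientations)) {
    out <- setdiff(onsets$orientation_deg, rec$orientations)
    if (length(out))
      fail(paste0("trial orientation ", out[1],
                  " not in the design's orientation set"))
  }
  invisible(rec)
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf(
    "<gaze_recording: run %d, %d samples at %g Hz (%.1f s), %d trials, %.2f%% missing>\n",
    x$run_index, length(x$time_ms), x$sample_rate,
    length(x$time_ms) / x$sample_rate,
    sum(x$events$kind == "trial_onset"), 100 * mean(x$missing)))
  invisible(x)
}

#' Screen geometry for pixel-to-degree conversion
#'
#' Defaults describe a 24-inch 1920 x 1080 display subtending 39.1 x 22.0
#' degrees of visual angle at 65 cm viewing distance.
#'
#' @param width_px,height_px screen resolution in pixels.
#' @param width_deg,height_deg screen extent in degrees of visual angle.
#' @param viewing_distance_cm eye-to-screen distance in cm.
#' @return An object of class `screen_geometry`.
#' @export
screen_geometry <- function(width_px = 1920, height_px = 1080,
                            width_deg = 39.1, height_deg = 22.0,
                            viewing_distance_cm = 65) {
  vals <- c(width_px, height_px, width_deg, height_deg, viewing_distance_cm)
  if (any(vals <= 0)) stop("screen geometry values must be positive",
                           call. = FALSE)
  structure(list(width_px = width_px, height_px = height_px,
                 width_deg = width_deg, height_deg = height_deg,
                 viewing_distance_cm = viewing_distance_cm),
            class = "screen_geometry")
}

#' Convert screen-pixel coordinates to degrees of visual angle
#'
#' Linear small-angle mapping: the offset from screen centre is scaled by the
#' per-axis degrees-per-pixel ratio. Pixel y grows downward; the output uses
#' +y up. Off-screen coordinates pass through.
#'
#' @param x_px,y_px pixel coordinates (vectors allowed).
#' @param geometry a [screen_geometry()].
#' @return data.frame with columns `x_deg`, `y_deg`.
#' @export
#' @examples
#' g <- screen_geometry()
#' pixels_to_degrees(960, 540, g)  # screen centre -> (0, 0)
pixels_to_degrees <- function(x_px, y_px, geometry = screen_geometry()) {
  stopifnot(inherits(geometry, "screen_geometry"))
  data.frame(
    x_deg = (x_px - geometry$width_px / 2) *
      (geometry$width_deg / geometry$width_px),
    y_deg = -(y_px - geometry$height_px / 2) *
      (geometry$height_deg / geometry$height_px))
}

IO_MAGIC <- "# gazedecode-recording v1"
SAMPLE_COLS <- c("time_ms", ALL_CHANNELS, "missing")
EVENT_COLS <- c("time_ms", "kind", "orientation_deg", "task_flag")

#' Write / read a gaze recording as self-describing delimited text
#'
#' The format is a plain-text file: a header of `# key: value` lines (sample
#' rate, run index, valid orientations, sample count), a `[samples]` section
#' (tab-separated, one row per sample, column order `time_ms, x_left, y_left,
#' x_right, y_right, pupil_left, pupil_right, missing`), and an `[events]`
#' section (`time_ms, kind, orientation_deg, task_flag`). Missing samples are
#' stored as the sentinel `NA` with `missing = 1` and restored to the mask on
#' read; the round trip is lossless for values, mask, and events.
#'
#' @param recording a `gaze_recording`.
#' @param path file path.
#' @return `read_recording` returns a `gaze_recording`; `write_recording`
#'   returns `path` invisibly.
#' @export
write_recording <- function(recording, path) {
  validate_recording(recording)
  writeLines(c(
    IO_MAGIC,
    sprintf("# sample_rate_hz: %.10g", recording$sample_rate),
    sprintf("# run_index: %d", recording$run_index),
    sprintf("# orientations: %s",
            if (is.null(recording$orientations)) "" else
              paste(format(recording$orientations, trim = TRUE),
                    collapse = ",")),
    sprintf("# n_samples: %d", length(recording$time_ms)),
    "[samples]"), path)
  samp <- data.table::as.data.table(recording[SAMPLE_COLS])
  samp$missing <- as.integer(samp$missing)
  # 17 significant digits guarantee an exact double round trip
  for (ch in ALL_CHANNELS) {
    v <- sprintf("%.17g", samp[[ch]])
    v[v == "nan"] <- "NA"
    data.table::set(samp, j = ch, value = v)
  }
  data.table::set(samp, j = "time_ms",
                  value = sprintf("%.12g", samp$time_ms))
  data.table::fwrite(samp, path, sep = "\t", na = "NA", append = TRUE,
                     col.names = TRUE, quote = FALSE)
  cat("[events]\n", file = path, append = TRUE)
  ev <- data.table::as.data.table(recording$events[, EVENT_COLS])
  ev$task_flag <- as.integer(ev$task_flag)
  data.table::fwrite(ev, path, sep = "\t", na = "NA", append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  lines <- readLines(path)
  perr <- function(line, msg)
    stop(sprintf("parse error at %s line %d: %s", path, line, msg),
         call. = FALSE)
  if (length(lines) < 7 || lines[1] != IO_MAGIC)
    perr(1, "not a gazedecode recording (bad magic line)")
  header_val <- function(key) {
    pat <- paste0("^# ", key, ": ?")
    hit <- grep(pat, lines[1:10], value = TRUE)
    if (!length(hit)) perr(1, paste("missing header field", key))
    sub(pat, "", hit[1])
  }
  sample_rate <- as.numeric(header_val("sample_rate_hz"))
  run_index <- as.integer(header_val("run_index"))
  ostr <- header_val("orientations")
  orientations <- if (nzchar(ostr))
    as.numeric(strsplit(ostr, ",")[[1]]) else NULL
  n_samples <- as.integer(header_val("n_samples"))
  if (is.na(sample_rate) || is.na(n_samples))
    perr(1, "malformed numeric header field")

  s_line <- match("[samples]", lines)
  e_line <- match("[events]", lines)
  if (is.na(s_line)) perr(1, "missing [samples] section")
  if (is.na(e_line)) perr(length(lines), "missing [events] section")
  if (e_line - s_line - 2L != n_samples)
    perr(s_line, sprintf("expected %d sample rows, found %d",
                         n_samples, e_line - s_line - 2L))

  samp <- data.table::fread(path, sep = "\t", skip = s_line,
                            nrows = n_samples, header = TRUE, na.strings = "NA")
  if (!identical(names(samp), SAMPLE_COLS))
    perr(s_line + 1L, "unexpected sample column order")
  ev <- data.table::fread(path, sep = "\t", skip = e_line, header = TRUE,
                          na.strings = "NA",
                          colClasses = list(character = "kind"))
  if (!identical(names(ev), EVENT_COLS))
    perr(e_line + 1L, "unexpected event column order")
  ev <- as.data.frame(ev)
  ev$task_flag <- as.logical(ev$task_flag)

  rec <- tryCatch(
    gaze_recording(sample_rate = sample_rate, time_ms = samp$time_ms,
                   x_left = samp$x_left, y_left = samp$y_left,
                   x_right = samp$x_right, y_right = samp$y_right,
                   pupil_left = samp$pupil_left,
                   pupil_right = samp$pupil_right,
                   missing = samp$missing == 1L, events = ev,
                   run_index = run_index, orientations = orientations),
    error = function(e) perr(s_line + 1L, conditionMessage(e)))
  rec
}
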