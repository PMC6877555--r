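#' Construct an experiment design
#'
#' Builds the session design used throughout the package: a fixed number of
#' runs, each presenting every grating orientation twice in random order, with
#' fixation periods flanking the trials. The defaults encode the standard
#' orientation-decoding design: 12 runs of 16 trials (8 orientations, 0 to
#' 157.5 degrees in 22.5-degree steps, each shown twice per run), 7-second
#' trials at a 2 Hz on/off presentation rate, 1 s inter-trial interval, 8 s of
#' fixation before and after the trials, sampled at 1000 Hz.
#'
#' In the `"active"` session 12.5% of trials are task trials: three per
#' orientation across the whole session, randomly allocated to runs, in which
#' one 250 ms `on' period between 1 and 6 s into the trial presents the
#' grating perturbed by 10 degrees. Passive sessions have no task trials.
#'
#' @param session_type `"passive"` or `"active"`.
#' @param n_runs number of runs.
#' @param orientations grating orientations in degrees, equally spaced on
#'   `[0, 180)`.
#' @param trials_per_run trials per run; must equal `2 * length(orientations)`.
#' @param trial_duration trial length in seconds.
#' @param inter_trial_interval gap between trials in seconds.
#' @param fixation_pre,fixation_post fixation-only periods at run start/end,
#'   seconds.
#' @param presentation_rate stimulus flicker rate in Hz.
#' @param on_ms,off_ms stimulus on/off durations in milliseconds.
#' @param task_fraction fraction of trials that are task trials (active only).
#' @param task_trials_per_orientation task trials per orientation across the
#'   session (active only).
#' @param perturbation_deg orientation perturbation on task trials, degrees.
#' @param sample_rate eye-tracker sampling rate in Hz.
#' @param seed optional integer seed for the random task-trial allocation of
#'   active designs; when `NULL` the current RNG stream is used.
#'
#' @return An object of class `experiment_design`.
#' @export
#' @examples
#' d <- make_design("passive")
#' total_trials(d)  # 192
make_design <- function(session_type = c("passive", "active"),
                        n_runs = 12,
                        orientations = seq(0, 157.5, by = 22.5),
                        trials_per_run = 2 * length(orientations),
                        trial_duration = 7,
                        inter_trial_interval = 1,
                        fixation_pre = 8,
                        fixation_post = 8,
                        presentation_rate = 2,
                        on_ms = 250,
                        off_ms = 250,
                        task_fraction = 0.125,
                        task_trials_per_orientation = 3,
                        perturbation_deg = 10,
                        sample_rate = 1000,
                        seed = NULL) {
  session_type <- match.arg(session_type)
  design <- structure(list(
    session_type = session_type,
    n_runs = as.integer(n_runs),
    orientations = as.numeric(orientations),
    trials_per_run = as.integer(trials_per_run),
    trial_duration = trial_duration,
    inter_trial_interval = inter_trial_interval,
    fixation_pre = fixation_pre,
    fixation_post = fixation_post,
    presentation_rate = presentation_rate,
    on_ms = on_ms,
    off_ms = off_ms,
    task_fraction = task_fraction,
    task_trials_per_orientation = as.integer(task_trials_per_orientation),
    perturbation_deg = perturbation_deg,
    sample_rate = sample_rate
  ), class = "experiment_design")
  validate_design(design)
  if (session_type == "active") {
    design$task_plan <- allocate_task_trials(design, seed)
  }
  design
}

validate_design <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  fail <- function(msg) stop("invalid design: ", msg, call. = FALSE)
  ori <- design$orientations
  k <- length(ori)
  if (k < 2) fail("need at least two orientations")
  if (any(ori < 0 | ori >= 180)) fail("orientations must lie in [0, 180)")
  step <- 180 / k
  if (max(abs(sort(ori) - seq(0, by = step, length.out = k))) > 1e-9)
    fail("orientations must be equally spaced on [0, 180) starting at 0")
  if (design$trials_per_run != 2L * k)
    fail("trials_per_run must equal 2 * number of orientations")
  if (design$n_runs < 1) fail("n_runs must be positive")
  for (f in c("trial_duration", "inter_trial_interval", "fixation_pre",
              "fixation_post", "presentation_rate", "sample_rate"))
    if (design[[f]] <= 0) fail(paste(f, "must be positive"))
  if (design$session_type == "active") {
    total <- design$n_runs * design$trials_per_run
    expected <- design$task_fraction * total
    if (abs(design$task_trials_per_orientation * k - expected) > 1e-9)
      fail(paste0("task_trials_per_orientation * n_orientations (",
                  design$task_trials_per_orientation * k,
                  ") must equal task_fraction * total trials (", expected, ")"))
    if (design$perturbation_deg <= 0) fail("perturbation_deg must be positive")
  }
  invisible(design)
}

# Randomly allocate the session's task trials to runs (at most the two
# occurrences a run holds per orientation), with a perturbed `on' period
# starting between 1 and 6 s into the trial.
allocate_task_trials <- function(design, seed = NULL) {
  draw <- function() {
    k <- design$task_trials_per_orientation
    on_starts <- seq(0, design$trial_duration - design$on_ms / 1000,
                     by = 1 / design$presentation_rate)
    allowed <- on_starts[on_starts >= 1 &
                         on_starts + design$on_ms / 1000 <= 6]
    plans <- lapply(design$orientations, function(ori) {
      # each run presents an orientation twice: slots are (run, occurrence)
      slots <- expand.grid(run = seq_len(design$n_runs), occurrence = 1:2)
      pick <- slots[sample.int(nrow(slots), k), ]
      data.frame(orientation = ori, run = pick$run,
                 occurrence = pick$occurrence,
                 perturb_onset_s = sample(allowed, k, replace = TRUE),
                 direction = sample(c(-1, 1), k, replace = TRUE))
    })
    out <- do.call(rbind, plans)
    rownames(out) <- NULL
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Total number of trials in a design
#'
#' @param design an `experiment_design`.
#' @return `n_runs * trials_per_run`.
#' @export
total_trials <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  design$n_runs * design$trials_per_run
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("<experiment_design: %s session>\n", x$session_type))
  cat(sprintf("  %d runs x %d trials (%d total), %d orientations\n",
              x$n_runs, x$trials_per_run, total_trials(x),
              length(x$orientations)))
  cat(sprintf("  trial %gs at %g Hz presentation, ITI %gs, fixation %g/%gs\n",
              x$trial_duration, x$presentation_rate, x$inter_trial_interval,
              x$fixation_pre, x$fixation_post))
  cat(sprintf("  sampling %g Hz\n", x$sample_rate))
  if (x$session_type == "active")
    cat(sprintf("  task trials: %d (%g%%), perturbation %g deg\n",
                nrow(x$task_plan), 100 * x$task_fraction, x$perturbation_deg))
  invisible(x)
}
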