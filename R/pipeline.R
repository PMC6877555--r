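#' Configuration of a full synthetic-cohort study
#'
#' Describes a cohort in which every participant completes an active and a
#' passive session (order counterbalanced by participant parity, recorded as
#' metadata). The bias amplitude of the active session may be a scalar or a
#' per-participant vector, letting half a cohort carry systematic eye
#' movements while the rest fixate cleanly.
#'
#' @param n_participants cohort size.
#' @param active_bias_mode bias geometry of the active session
#'   (`"none"`, `"along_axis"`, `"orthogonal_axis"`).
#' @param active_bias_amplitude excursion amplitude in degrees; scalar or
#'   length-`n_participants` vector.
#' @param passive_bias_amplitude amplitude for the passive session (normally
#'   0: passive fixation shows no systematic eye movements).
#' @param passive_bias_mode bias geometry of the passive session.
#' @param noise list of [bias_model()] noise arguments shared by all
#'   participants (drift, microsaccade, blink, pupil settings).
#' @param design_overrides list of [make_design()] arguments overriding the
#'   standard design for both sessions (e.g. fewer runs for quick pilots);
#'   active-session task constraints must stay consistent.
#' @param n_perm label permutations per participant.
#' @param master_seed integer master seed; all per-participant, per-stage
#'   seeds are derived from it.
#' @param run_sweep also run the threshold sweeps (slower)?
#' @param sweep_method,sweep_grid passed to [threshold_sweep()] when
#'   `run_sweep` is `TRUE`.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_participants = 28,
                         active_bias_mode = "along_axis",
                         active_bias_amplitude = 1.0,
                         passive_bias_amplitude = 0,
                         passive_bias_mode = "none",
                         noise = list(),
                         design_overrides = list(),
                         n_perm = 1000,
                         master_seed = 1L,
                         run_sweep = FALSE,
                         sweep_method = "distance",
                         sweep_grid = NULL) {
  stopifnot(n_participants >= 1)
  amp <- rep_len(active_bias_amplitude, n_participants)
  structure(list(n_participants = as.integer(n_participants),
                 active_bias_mode = active_bias_mode,
                 active_bias_amplitude = amp,
                 passive_bias_amplitude = passive_bias_amplitude,
                 passive_bias_mode = passive_bias_mode,
                 noise = noise, design_overrides = design_overrides,
                 n_perm = n_perm,
                 master_seed = as.integer(master_seed),
                 run_sweep = run_sweep, sweep_method = sweep_method,
                 sweep_grid = sweep_grid),
            class = "study_config")
}

# One master seed deterministically spawns per-participant, per-stage seeds,
# kept within the 32-bit integer range.
derive_seed <- function(master, participant, stage) {
  as.integer((as.double(master) * 10007 + participant * 131 + stage) %%
               2147483647)
}

#' Run a complete synthetic study
#'
#' For every participant: simulate the active and passive sessions,
#' preprocess (blink repair, low-pass, downsample, epoch, run-median
#' centering), extract features (task trials dropped in the active session),
#' decode orientation with the permutation test, and measure eye-movement
#' amplitude. Task-trial behaviour (hits on perturbed trials, false alarms
#' elsewhere) is simulated per participant to produce task accuracy,
#' sensitivity, and specificity. At the cohort level: paired signed-rank
#' test of active vs passive decoding accuracy, per-session tests against
#' chance level, Spearman correlations (with Fisher-z CIs) of decoding
#' accuracy with task performance and eye-movement amplitude, and a
#' session-order check on order-grouped difference scores. A participant
#' whose simulation or analysis fails is isolated and reported, not fatal.
#'
#' @param config a [study_config()].
#' @param progress print per-participant progress lines?
#' @return An object of class `study_report`: `participants` (one row per
#'   participant), `cohort` (list of `group_stats_result`s), `sweeps`
#'   (optional), `config`.
#' @export
run_study <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  chance <- NA_real_
  rows <- list()
  sweeps <- list()
  for (p in seq_len(config$n_participants)) {
    res <- tryCatch(run_participant(config, p),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      warning(sprintf("participant %d failed: %s", p, res), call. = FALSE)
      rows[[p]] <- data.frame(participant = p, failed = TRUE,
                              order = if (p %% 2 == 1) "active_first"
                                      else "passive_first")
      next
    }
    chance <- res$chance
    rows[[p]] <- res$row
    if (config$run_sweep) sweeps[[p]] <- res$sweep_input
    if (progress)
      message(sprintf("participant %d: active %.1f%%, passive %.1f%%",
                      p, res$row$active_accuracy, res$row$passive_accuracy))
  }
  participants <- data.table::rbindlist(rows, fill = TRUE)
  participants <- as.data.frame(participants)
  ok <- !(participants$failed %in% TRUE)
  if ("active_accuracy" %in% names(participants)) {
    ok <- ok & !is.na(participants$active_accuracy)
  } else ok <- rep(FALSE, nrow(participants))
  cohort <- NULL
  if (sum(ok) >= 6) {
    pa <- participants[ok, ]
    cohort <- list(
      active_vs_passive = wilcoxon_paired(pa$active_accuracy,
                                          pa$passive_accuracy),
      active_vs_chance = wilcoxon_vs_chance(pa$active_accuracy, chance),
      passive_vs_chance = wilcoxon_vs_chance(pa$passive_accuracy, chance),
      task_acc_vs_decoding = spearman_ci(pa$task_accuracy,
                                         pa$active_accuracy),
      sensitivity_vs_decoding = spearman_ci(pa$sensitivity,
                                            pa$active_accuracy),
      specificity_vs_decoding = spearman_ci(pa$specificity,
                                            pa$active_accuracy),
      amplitude_vs_decoding = spearman_ci(pa$active_amplitude,
                                          pa$active_accuracy),
      order_effect = session_order_test(pa)
    )
  }
  sweep_res <- NULL
  sweeps <- Filter(Negate(is.null), sweeps)  # drop failed participants
  if (config$run_sweep && length(sweeps))
    sweep_res <- threshold_sweep(sweeps, method = config$sweep_method,
                                 grid = config$sweep_grid,
                                 seed = config$master_seed)
  structure(list(participants = participants, cohort = cohort,
                 sweeps = sweep_res, chance = chance, config = config),
            class = "study_report")
}

run_participant <- function(config, p) {
  ms <- config$master_seed
  sessions <- list()
  for (ses in c("active", "passive")) {
    stage0 <- if (ses == "active") 0L else 10L
    mode <- if (ses == "active") config$active_bias_mode
            else config$passive_bias_mode
    amp <- if (ses == "active") config$active_bias_amplitude[p]
           else config$passive_bias_amplitude
    design <- do.call(make_design, c(
      list(ses, seed = derive_seed(ms, p, stage0 + 1L)),
      config$design_overrides))
    bias <- do.call(bias_model, c(
      list(mode = if (amp > 0) mode else "none", bias_amplitude = amp,
           seed = derive_seed(ms, p, stage0 + 2L)),
      config$noise))
    session <- simulate_session(design, bias)
    epochs <- preprocess_session(session)
    feats <- extract_features(epochs, drop_task_trials = TRUE,
                              session_type = ses)
    perm <- permutation_test(feats, n_perm = config$n_perm,
                             seed = derive_seed(ms, p, stage0 + 3L))
    amplitude <- session_amplitude(
      Filter(function(e) !isTRUE(e$task), epochs))
    sessions[[ses]] <- list(design = design, epochs = epochs, perm = perm,
                            amplitude = amplitude)
  }
  task <- simulate_task_behaviour(sessions$active$design,
                                  derive_seed(ms, p, 21L))
  k <- length(sessions$active$design$orientations)
  row <- data.frame(
    participant = p, failed = FALSE,
    order = if (p %% 2 == 1) "active_first" else "passive_first",
    active_accuracy = sessions$active$perm$observed,
    active_p = sessions$active$perm$p_value,
    active_significant = sessions$active$perm$significant,
    passive_accuracy = sessions$passive$perm$observed,
    passive_p = sessions$passive$perm$p_value,
    passive_significant = sessions$passive$perm$significant,
    active_amplitude = sessions$active$amplitude,
    passive_amplitude = sessions$passive$amplitude,
    task_accuracy = task$accuracy, sensitivity = task$sensitivity,
    specificity = task$specificity,
    bias_amplitude = config$active_bias_amplitude[p])
  list(row = row, chance = 100 / k,
       sweep_input = list(active = sessions$active$epochs,
                          passive = sessions$passive$epochs))
}

# Simulated perturbation-detection behaviour: per-participant hit rate drawn
# in the high-performance range typical of an easy 10-degree discrimination,
# with a low false-alarm rate on non-task trials.
simulate_task_behaviour <- function(design, seed) {
  withr::with_seed(seed, {
    n_task <- nrow(design$task_plan)
    n_total <- total_trials(design)
    hit_rate <- runif(1, 0.84, 0.99)
    fa_rate <- runif(1, 0.005, 0.04)
    hits <- rbinom(1, n_task, hit_rate)
    fas <- rbinom(1, n_total - n_task, fa_rate)
    list(accuracy = 100 * (hits + (n_total - n_task - fas)) / n_total,
         sensitivity = 100 * hits / n_task,
         specificity = 100 * (n_total - n_task - fas) / (n_total - n_task))
  })
}

# Counterbalancing check: pair the i-th active-first participant's
# active-minus-passive difference with the i-th passive-first participant's,
# and test the paired differences for a shift.
session_order_test <- function(participants) {
  d <- participants$active_accuracy - participants$passive_accuracy
  g1 <- d[participants$order == "active_first"]
  g2 <- d[participants$order == "passive_first"]
  m <- min(length(g1), length(g2))
  if (m < 6) return(NULL)
  out <- wilcoxon_paired(g1[seq_len(m)], g2[seq_len(m)])
  out$test <- "session_order"
  out
}

#' @export
print.study_report <- function(x, ...) {
  ok <- if ("active_accuracy" %in% names(x$participants))
    !is.na(x$participants$active_accuracy) else logical(nrow(x$participants))
  cat(sprintf("<study_report: %d participants (%d analysed)>\n",
              nrow(x$participants), sum(ok)))
  if (sum(ok)) {
    cat(sprintf("  active:  median %.1f%%, %d/%d significant\n",
                median(x$participants$active_accuracy[ok]),
                sum(x$participants$active_significant[ok]), sum(ok)))
    cat(sprintf("  passive: median %.1f%%, %d/%d significant\n",
                median(x$participants$passive_accuracy[ok]),
                sum(x$participants$passive_significant[ok]), sum(ok)))
  }
  if (!is.null(x$cohort)) {
    cat(sprintf("  active vs passive: p = %.3g\n",
                x$cohort$active_vs_passive$p_value))
    cat(sprintf("  amplitude ~ decoding: rho = %.2f [%.2f, %.2f]\n",
                x$cohort$amplitude_vs_decoding$statistic,
                x$cohort$amplitude_vs_decoding$ci_low,
                x$cohort$amplitude_vs_decoding$ci_high))
  }
  invisible(x)
}

#' Per-orientation mean gaze trajectories
#'
#' Sample-wise mean of the binocular-average gaze path over all trials of
#' each orientation — the averaged trajectories that make systematic,
#' stimulus-aligned eye movements visible. Orientations without trials are
#' omitted with a warning.
#'
#' @param epochs list of `trial_epoch` objects.
#' @param orientations orientations to include; defaults to those present.
#' @return data.frame with columns `orientation`, `time_s`, `x`, `y`.
#' @export
mean_gaze_paths <- function(epochs, orientations = NULL) {
  stopifnot(length(epochs) > 0)
  labs <- vapply(epochs, function(e) e$orientation, numeric(1))
  if (is.null(orientations)) orientations <- sort(unique(labs))
  out <- list()
  for (ori in orientations) {
    idx <- which(labs == ori)
    if (length(idx) == 0) {
      warning("no trials for orientation ", ori, "; omitted", call. = FALSE)
      next
    }
    bx <- rowMeans(vapply(epochs[idx], function(e)
      (e$data[, "x_left"] + e$data[, "x_right"]) / 2,
      numeric(nrow(epochs[[idx[1]]]$data))))
    by <- rowMeans(vapply(epochs[idx], function(e)
      (e$data[, "y_left"] + e$data[, "y_right"]) / 2,
      numeric(nrow(epochs[[idx[1]]]$data))))
    out[[length(out) + 1L]] <- data.frame(
      orientation = ori,
      time_s = (seq_along(bx) - 1) / epochs[[idx[1]]]$sample_rate,
      x = bx, y = by)
  }
  do.call(rbind, out)
}

#' Principal axis of a planar trajectory
#'
#' Angle (degrees, mod 180) of the leading eigenvector of the 2-D covariance
#' of the points — the axis along which a gaze path is elongated. Used to
#' check that biased trajectories align with the stimulus orientation.
#'
#' @param x,y coordinates of the path.
#' @return Angle in degrees within `[0, 180)`.
#' @export
principal_axis_angle <- function(x, y) {
  cm <- cbind(x - mean(x), y - mean(y))
  ev <- eigen(crossprod(cm) / length(x), symmetric = TRUE)$vectors[, 1]
  (atan2(ev[2], ev[1]) * 180 / pi) %% 180
}
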