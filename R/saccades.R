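#' Per-sample gaze velocity
#'
#' Computes eye velocity with the 5-point moving-window estimator
#' `v[n] = (p[n+2] + p[n+1] - p[n-1] - p[n-2]) / (6 * dt)` per component and
#' eye, which suppresses sample-to-sample noise while remaining exact for
#' linear motion. Speed is the Euclidean norm per eye; the binocular series
#' is the mean of the two eyes. The two samples at each edge are padded with
#' the nearest interior value.
#'
#' @param epoch a `trial_epoch` (or any object with `data` and
#'   `sample_rate`).
#' @return A list with per-sample components `vx_left, vy_left, vx_right,
#'   vy_right`, per-eye speeds `speed_left, speed_right`, and the binocular
#'   mean `speed` (degrees/s).
#' @export
gaze_velocity <- function(epoch) {
  n <- nrow(epoch$data)
  if (n < 5) stop("epoch too short for the 5-point velocity estimator",
                  call. = FALSE)
  dt <- 1 / epoch$sample_rate
  five_point <- function(p) {
    v <- numeric(n)
    i <- 3:(n - 2)
    v[i] <- (p[i + 2] + p[i + 1] - p[i - 1] - p[i - 2]) / (6 * dt)
    v[1:2] <- v[3]
    v[(n - 1):n] <- v[n - 2]
    v
  }
  vx_l <- five_point(epoch$data[, "x_left"])
  vy_l <- five_point(epoch$data[, "y_left"])
  vx_r <- five_point(epoch$data[, "x_right"])
  vy_r <- five_point(epoch$data[, "y_right"])
  sp_l <- sqrt(vx_l^2 + vy_l^2)
  sp_r <- sqrt(vx_r^2 + vy_r^2)
  list(vx_left = vx_l, vy_left = vy_l, vx_right = vx_r, vy_right = vy_r,
       speed_left = sp_l, speed_right = sp_r, speed = (sp_l + sp_r) / 2)
}

# Median-based spread estimate sqrt(median(v^2) - median(v)^2), robust to
# the saccadic outliers the threshold is meant to find.
median_spread <- function(v) sqrt(max(median(v^2) - median(v)^2, 0))

#' Detect microsaccades with a median-based elliptic velocity threshold
#'
#' Per eye, velocity samples are compared against an ellipse with semi-axes
#' `lambda * sigma_x` and `lambda * sigma_y`, where `sigma` is the
#' median-based spread of each velocity component; samples outside the
#' ellipse that form runs of at least the minimum duration become candidate
#' events. An event is kept as binocular when a left-eye and a right-eye
#' event overlap in time by at least one sample. Event amplitude is the
#' displacement between onset and offset gaze positions.
#'
#' @param epoch a `trial_epoch`.
#' @param lambda threshold multiplier for the ellipse semi-axes.
#' @param min_duration_ms minimum event duration, milliseconds.
#' @param binocular_only return only events passing the binocular criterion?
#' @return data.frame with one row per event: `eye`, `onset`, `offset`
#'   (sample indices), `amplitude` (degrees), `peak_velocity` (degrees/s),
#'   `binocular`.
#' @export
detect_microsaccades <- function(epoch, lambda = 6, min_duration_ms = 6,
                                 binocular_only = TRUE) {
  vel <- gaze_velocity(epoch)
  min_samp <- max(1L, ceiling(min_duration_ms * epoch$sample_rate / 1000))
  one_eye <- function(eye) {
    vx <- vel[[paste0("vx_", eye)]]
    vy <- vel[[paste0("vy_", eye)]]
    ex <- lambda * median_spread(vx)
    ey <- lambda * median_spread(vy)
    if (ex <= .Machine$double.eps || ey <= .Machine$double.eps) {
      warning("zero velocity spread in ", eye,
              " eye; no events detectable", call. = FALSE)
      return(NULL)
    }
    outside <- (vx / ex)^2 + (vy / ey)^2 > 1
    r <- rle(outside)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_samp
    if (!any(keep)) return(NULL)
    onset <- starts[keep]; offset <- ends[keep]
    xs <- epoch$data[, paste0("x_", eye)]
    ys <- epoch$data[, paste0("y_", eye)]
    sp <- vel[[paste0("speed_", eye)]]
    data.frame(eye = eye, onset = onset, offset = offset,
               amplitude = sqrt((xs[offset] - xs[onset])^2 +
                                (ys[offset] - ys[onset])^2),
               peak_velocity = vapply(seq_along(onset), function(i)
                 max(sp[onset[i]:offset[i]]), numeric(1)))
  }
  left <- one_eye("left")
  right <- one_eye("right")
  empty <- data.frame(eye = character(), onset = integer(),
                      offset = integer(), amplitude = numeric(),
                      peak_velocity = numeric(), binocular = logical())
  if (is.null(left) && is.null(right)) return(empty)
  overlaps <- function(a, b) {
    if (is.null(a) || is.null(b)) return(rep(FALSE, NROW(a)))
    vapply(seq_len(nrow(a)), function(i)
      any(a$onset[i] <= b$offset & b$onset <= a$offset[i]), logical(1))
  }
  if (!is.null(left)) left$binocular <- overlaps(left, right)
  if (!is.null(right)) right$binocular <- overlaps(right, left)
  out <- rbind(left, right)
  if (binocular_only) out <- out[out$binocular, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Binocular-average per-sample radial distance from fixation.
binocular_distance <- function(epoch) {
  bx <- (epoch$data[, "x_left"] + epoch$data[, "x_right"]) / 2
  by <- (epoch$data[, "y_left"] + epoch$data[, "y_right"]) / 2
  sqrt(bx^2 + by^2)
}

#' Remove trials violating fixation, by distance or velocity
#'
#' `filter_by_distance()` removes a trial iff any sample's binocular-average
#' gaze position lies further from fixation than `threshold` degrees (a
#' circle around fixation beyond which trials are discarded).
#' `filter_by_velocity()` removes a trial iff the binocular eye speed exceeds
#' `threshold` degrees/s at any sample (a saccade was made). Both then decode
#' orientation from the kept trials, so the report shows what the filtered
#' analysis supports; with `threshold = Inf` all trials are kept and the
#' decoding equals the unfiltered result.
#'
#' @param epochs list of centred `trial_epoch` objects.
#' @param threshold threshold in degrees (distance) or degrees/s (velocity);
#'   must be non-negative.
#' @param decode run [crossval_decode()] on the kept trials?
#' @param drop_task_trials passed to [extract_features()].
#' @param seed decoding seed.
#' @return An object of class `filter_report`: `method`, `threshold`,
#'   `kept_trials` (indices into `epochs`), `kept_fraction`, and `decoding`
#'   (a `decoding_result`, possibly the insufficient-data sentinel, or `NULL`
#'   when `decode = FALSE`).
#' @export
filter_by_distance <- function(epochs, threshold, decode = TRUE,
                               drop_task_trials = TRUE, seed = 1L) {
  filter_trials(epochs, threshold, "distance", decode, drop_task_trials, seed)
}

#' @rdname filter_by_distance
#' @export
filter_by_velocity <- function(epochs, threshold, decode = TRUE,
                               drop_task_trials = TRUE, seed = 1L) {
  filter_trials(epochs, threshold, "velocity", decode, drop_task_trials, seed)
}

filter_trials <- function(epochs, threshold, method, decode,
                          drop_task_trials, seed) {
  if (threshold < 0) stop("threshold must be non-negative", call. = FALSE)
  stopifnot(length(epochs) > 0)
  crit <- switch(method,
    distance = function(e) max(binocular_distance(e)),
    velocity = function(e) max(gaze_velocity(e)$speed))
  kept <- which(vapply(epochs, crit, numeric(1)) <= threshold)
  decoding <- NULL
  if (decode) {
    decoding <- if (length(kept) == 0) {
      structure(list(fold_accuracies = NULL, accuracy = NA_real_,
                     n_per_class = integer(), seed = as.integer(seed),
                     feasible = FALSE, reason = "no trials kept"),
                class = "decoding_result")
    } else {
      feats <- tryCatch(
        extract_features(epochs[kept], drop_task_trials = drop_task_trials),
        error = function(e) NULL)
      all_classes <- unique(vapply(epochs, function(e) e$orientation,
                                   numeric(1)))
      if (is.null(feats)) {
        structure(list(fold_accuracies = NULL, accuracy = NA_real_,
                       n_per_class = integer(), seed = as.integer(seed),
                       feasible = FALSE, reason = "no non-task trials kept"),
                  class = "decoding_result")
      } else if (!all(all_classes %in% feats$orientation)) {
        # a class lost every trial: decoding the remainder would silently
        # change the chance level, so report insufficient data instead
        structure(list(fold_accuracies = NULL, accuracy = NA_real_,
                       n_per_class = integer(), seed = as.integer(seed),
                       feasible = FALSE,
                       reason = "insufficient data: a class lost all trials"),
                  class = "decoding_result")
      } else crossval_decode(feats, seed = seed)
    }
  }
  structure(list(method = method, threshold = threshold, kept_trials = kept,
                 kept_fraction = length(kept) / length(epochs),
                 decoding = decoding),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  acc <- if (is.null(x$decoding)) "not decoded"
         else if (!x$decoding$feasible) "insufficient data"
         else sprintf("accuracy %.1f%%", x$decoding$accuracy)
  cat(sprintf("<filter_report: %s <= %g, kept %.0f%%, %s>\n",
              x$method, x$threshold, 100 * x$kept_fraction, acc))
  invisible(x)
}

#' Sweep trial-removal thresholds over a cohort
#'
#' For each threshold in the grid (plus an unfiltered `none` condition,
#' threshold `Inf`), filters every participant's active and passive epochs,
#' decodes the kept trials, and compares the two sessions across
#' participants with a paired Wilcoxon signed-rank test, Bonferroni-corrected
#' across the swept conditions. Participants for whom too many trials were
#' removed to decode are flagged (`feasible = FALSE`), never given a numeric
#' accuracy, and drop out of that threshold's paired comparison.
#'
#' @param cohort list of participants; each element is a list with `active`
#'   and `passive` epoch lists.
#' @param method `"distance"` or `"velocity"`.
#' @param grid numeric thresholds to sweep (non-empty).
#' @param seed decoding seed.
#' @param alpha significance criterion before correction.
#' @return An object of class `threshold_sweep`: `accuracies` (long
#'   data.frame: participant, threshold, session, accuracy, feasible) and
#'   `comparison` (per threshold: n pairs, medians, p, Bonferroni-corrected
#'   significance).
#' @export
threshold_sweep <- function(cohort, method = c("distance", "velocity"),
                            grid = NULL, seed = 1L, alpha = 0.05) {
  method <- match.arg(method)
  if (is.null(grid))
    grid <- if (method == "distance") c(0.25, 0.5, 1, 2, 4)
            else c(10, 20, 30, 50, 100)
  if (length(grid) == 0) stop("empty threshold grid", call. = FALSE)
  stopifnot(length(cohort) > 0)
  thresholds <- c(sort(grid), Inf)
  ffun <- if (method == "distance") filter_by_distance else filter_by_velocity
  rows <- list()
  for (p in seq_along(cohort)) {
    for (th in thresholds) {
      for (ses in c("active", "passive")) {
        rep_ <- ffun(cohort[[p]][[ses]], th, decode = TRUE, seed = seed)
        rows[[length(rows) + 1L]] <- data.frame(
          participant = p, threshold = th, session = ses,
          kept_fraction = rep_$kept_fraction,
          feasible = rep_$decoding$feasible,
          accuracy = if (rep_$decoding$feasible) rep_$decoding$accuracy
                     else NA_real_)
      }
    }
  }
  acc <- do.call(rbind, rows)
  comparison <- do.call(rbind, lapply(thresholds, function(th) {
    a <- acc[acc$threshold == th & acc$session == "active", ]
    b <- acc[acc$threshold == th & acc$session == "passive", ]
    ok <- a$feasible & b$feasible
    p_val <- if (sum(ok) >= 6)
      wilcoxon_paired(a$accuracy[ok], b$accuracy[ok])$p_value else NA_real_
    data.frame(threshold = th, n_pairs = sum(ok),
               median_active = median(a$accuracy[ok]),
               median_passive = median(b$accuracy[ok]),
               p_value = p_val)
  }))
  comparison$significant <- !is.na(comparison$p_value) &
    comparison$p_value < alpha / length(thresholds)
  structure(list(method = method, grid = grid, accuracies = acc,
                 comparison = comparison, alpha = alpha),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf("<threshold_sweep: %s over %d thresholds + none>\n",
              x$method, length(x$grid)))
  print(x$comparison)
  invisible(x)
}
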