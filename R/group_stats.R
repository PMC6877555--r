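#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided signed-rank test on the paired differences `a - b`. Zero
#' differences are discarded before ranking (the classic convention, which
#' keeps the exact null well defined). The reported statistic is
#' `min(T+, T-)`, the smaller of the positive- and negative-rank sums. The
#' p-value is exact for small samples: by the closed-form signed-rank
#' distribution when the absolute differences are tie-free and `n <= 25`, by
#' full enumeration of all `2^n` sign assignments when ties are present and
#' `n <= 14`; otherwise the normal approximation with continuity correction
#' (and tie correction of the variance) is used.
#'
#' @param a,b paired numeric vectors of equal length (>= 6 recommended).
#' @param alpha significance criterion recorded in the result.
#' @return An object of class `group_stats_result` with fields `test`,
#'   `statistic`, `n` (pairs after zero removal), `p_value`, `alpha`.
#' @export
wilcoxon_paired <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1", call. = FALSE)
    return(group_stats_result("wilcoxon_paired", NA_real_, 0L, 1, alpha))
  }
  r <- rank(abs(d))
  t_plus <- sum(r[d > 0])
  t_minus <- n * (n + 1) / 2 - t_plus
  stat <- min(t_plus, t_minus)
  ties <- anyDuplicated(abs(d)) > 0
  if (!ties && n <= 25) {
    p <- 2 * min(psignrank(t_plus, n), 1 - psignrank(t_plus - 1, n))
  } else if (ties && n <= 14) {
    p <- signed_rank_enumeration_p(r, t_plus)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(abs(d))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (t_plus - mu - sign(t_plus - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
  }
  group_stats_result("wilcoxon_paired", stat, n, min(p, 1), alpha)
}

# Exact two-sided p over all 2^n sign assignments of the ranked |d|,
# honouring average ranks under ties.
signed_rank_enumeration_p <- function(ranks, t_plus) {
  n <- length(ranks)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  t_all <- as.vector(signs %*% ranks)
  2 * min(mean(t_all <= t_plus), mean(t_all >= t_plus))
}

#' Wilcoxon signed-rank test against chance level
#'
#' One-sample version of [wilcoxon_paired()] on difference scores with a
#' fixed chance level (12.5% for 8 balanced classes).
#'
#' @param accuracies numeric vector of accuracies in percent.
#' @param chance chance level in percent.
#' @param alpha significance criterion.
#' @return A `group_stats_result` (test `"wilcoxon_vs_chance"`).
#' @export
wilcoxon_vs_chance <- function(accuracies, chance = 12.5, alpha = 0.05) {
  out <- wilcoxon_paired(accuracies, rep(chance, length(accuracies)),
                         alpha = alpha)
  out$test <- "wilcoxon_vs_chance"
  out
}

#' Spearman rank correlation with a Fisher-z confidence interval
#'
#' Rank correlation with average ranks for ties; two-sided p-value via the
#' t approximation. The confidence interval is constructed on the Fisher
#' z-transform of rho with standard error `1 / sqrt(n - 3)` and
#' back-transformed; this is an approximation whose coverage for rank
#' correlations is nominal, not exact.
#'
#' @param x,y numeric vectors of equal length (>= 4).
#' @param alpha two-sided significance level; the CI has level `1 - alpha`.
#' @return A `group_stats_result` with `statistic` = rho and `ci_low`,
#'   `ci_high` populated.
#' @export
spearman_ci <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (sd(x) == 0 || sd(y) == 0)
    stop("rank correlation undefined for a constant input", call. = FALSE)
  n <- length(x)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  rho <- unname(ct$estimate)
  z <- atanh(min(max(rho, -1 + 1e-15), 1 - 1e-15))
  se <- 1 / sqrt(n - 3)
  ci <- tanh(z + c(-1, 1) * qnorm(1 - alpha / 2) * se)
  out <- group_stats_result("spearman", rho, n, unname(ct$p.value), alpha)
  out$ci_low <- ci[1]
  out$ci_high <- ci[2]
  out
}

#' Bonferroni correction
#'
#' Flags `p[i] < alpha / m` with `m = length(p)`.
#'
#' @param p_values non-empty numeric vector of p-values.
#' @param alpha family-wise criterion.
#' @return Logical vector of corrected significance flags.
#' @export
bonferroni <- function(p_values, alpha = 0.05) {
  stopifnot(length(p_values) > 0)
  p_values < alpha / length(p_values)
}

group_stats_result <- function(test, statistic, n, p_value, alpha) {
  structure(list(test = test, statistic = statistic, n = n,
                 p_value = p_value, alpha = alpha,
                 ci_low = NULL, ci_high = NULL),
            class = "group_stats_result")
}

#' @export
print.group_stats_result <- function(x, ...) {
  ci <- if (!is.null(x$ci_low))
    sprintf(", %d%% CI [%.2f, %.2f]", round(100 * (1 - x$alpha)),
            x$ci_low, x$ci_high) else ""
  cat(sprintf("<%s: statistic = %.3g, n = %d, p = %.3g%s>\n",
              x$test, x$statistic, x$n, x$p_value, ci))
  invisible(x)
}
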