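# Independent oracle: exhaustive enumeration of all 2^n sign assignments.
enumerate_signed_rank_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  t_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  t_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(t_all <= t_obs), mean(t_all >= t_obs)))
}

test_that("degenerate and one-sided paired samples behave as expected", {
  a <- c(1, 2, 3, 4, 5, 6, 7, 8)
  expect_warning(res <- wilcoxon_paired(a, a), "zero")
  expect_equal(res$p_value, 1)

  res2 <- wilcoxon_paired(a + 2, a)
  expect_equal(res2$p_value, 2 / 2^8)  # all ranks one-signed: minimal p
  expect_equal(res2$statistic, 0)
})

test_that("signed-rank p matches exhaustive sign enumeration", {
  cases <- list(
    list(a = c(3.1, 2.2, 5.0, 4.4, 1.2, 6.6, 0.3, 2.8),
         b = c(2.0, 2.9, 4.1, 1.0, 3.3, 5.0, 1.1, 0.4)),
    list(a = c(10, 12, 9, 14, 8, 11, 13, 7, 15, 10.5),
         b = c(9, 13, 8, 10, 9.5, 10, 12, 9, 11, 10)),
    # ties in |differences|: enumeration with average ranks
    list(a = c(5, 6, 7, 8, 9, 10, 11),
         b = c(4, 5, 6, 9, 8, 8, 13))
  )
  for (cs in cases) {
    expect_equal(wilcoxon_paired(cs$a, cs$b)$p_value,
                 enumerate_signed_rank_p(cs$a, cs$b))
  }
})

test_that("two-sided p is symmetric in the argument order", {
  withr::with_seed(8, {
    a <- rnorm(12); b <- rnorm(12)
  })
  expect_equal(wilcoxon_paired(a, b)$p_value, wilcoxon_paired(b, a)$p_value)
})

test_that("large samples fall back to the corrected normal approximation", {
  withr::with_seed(9, {
    a <- rnorm(40, mean = 0.4); b <- rnorm(40)
  })
  mine <- wilcoxon_paired(a, b)
  ref <- suppressWarnings(
    stats::wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = TRUE))
  expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-10)
})

test_that("comparison against chance level wraps the paired test", {
  accs <- rep(12.5, 8)
  expect_warning(res <- wilcoxon_vs_chance(accs), "zero")
  expect_equal(res$p_value, 1)

  res2 <- wilcoxon_vs_chance(rep(50, 8))
  expect_equal(res2$p_value, 2 / 2^8)

  withr::with_seed(10, accs3 <- 12.5 + rnorm(9, 2, 4))
  expect_equal(wilcoxon_vs_chance(accs3)$p_value,
               enumerate_signed_rank_p(accs3, rep(12.5, 9)))
})

test_that("rank correlation handles monotone and constant inputs", {
  x <- 1:10
  expect_equal(spearman_ci(x, x^3)$statistic, 1)
  expect_equal(spearman_ci(x, -sqrt(x))$statistic, -1)
  expect_error(spearman_ci(rep(1, 10), x), "constant")
})

test_that("rank correlation is invariant under monotone transforms", {
  withr::with_seed(11, {
    x <- rnorm(25); y <- 0.5 * x + rnorm(25)
  })
  base <- spearman_ci(x, y)
  expect_equal(spearman_ci(exp(x), y)$statistic, base$statistic)
  expect_equal(spearman_ci(x, y^3 + 5 * y)$statistic, base$statistic)
  expect_equal(spearman_ci(exp(x), y)$ci_low, base$ci_low)
})

test_that("the CI follows the Fisher-z construction", {
  withr::with_seed(12, {
    x <- rnorm(28); y <- 0.6 * x + rnorm(28)
  })
  res <- spearman_ci(x, y)
  z <- atanh(res$statistic)
  se <- 1 / sqrt(28 - 3)
  expect_equal(res$ci_low, tanh(z - qnorm(0.975) * se))
  expect_equal(res$ci_high, tanh(z + qnorm(0.975) * se))
  # the published-scale case: rho = 0.51 at n = 28 gives roughly [.17, .74]
  expect_equal(round(tanh(atanh(0.51) + c(-1, 1) * qnorm(0.975) / 5), 2),
               c(0.17, 0.74))
})

test_that("Bonferroni flags follow p < alpha / m and shrink the flag set", {
  expect_true(bonferroni(0.04))
  expect_equal(bonferroni(c(0.02, 0.2, 0.3, 0.4, 0.5)),
               c(FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(bonferroni(c(0.009, 0.2, 0.3, 0.4, 0.5)),
               c(TRUE, FALSE, FALSE, FALSE, FALSE))
  withr::with_seed(13, p <- runif(20))
  expect_true(all(which(bonferroni(p)) %in% which(p < 0.05)))
  expect_error(bonferroni(numeric(0)))
})
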