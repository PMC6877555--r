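test_that("well-separated classes decode nearly perfectly", {
  f <- make_features(n_per_class = 20, sep = 10, seed = 2)
  res <- crossval_decode(f, seed = 1)
  expect_true(res$feasible)
  expect_gt(res$accuracy, 95)
  expect_length(res$fold_accuracies, 10)
  expect_equal(res$accuracy, mean(res$fold_accuracies))
})

test_that("pure-noise features decode at chance on average", {
  accs <- vapply(1:20, function(s)
    crossval_decode(make_features(n_per_class = 24, sep = 0, seed = s),
                    seed = s)$accuracy, numeric(1))
  expect_lt(abs(mean(accs) - 12.5), 3)
})

test_that("a class with fewer trials than folds yields the sentinel", {
  f <- make_features(n_per_class = 12, k = 4, seed = 3)
  keep <- c(which(f$orientation == 0)[1:5], which(f$orientation != 0))
  f$x <- f$x[keep, ]; f$orientation <- f$orientation[keep]
  f$run <- f$run[keep]
  res <- crossval_decode(f, seed = 1)
  expect_false(res$feasible)
  expect_true(is.na(res$accuracy))
  expect_match(res$reason, "insufficient")
})

test_that("folds are stratified within one trial of the ideal count", {
  for (seed in 1:5) {
    labels <- withr::with_seed(seed, sample(rep(1:8, times = c(24, 24, 21,
      23, 22, 24, 20, 24))))
    folds <- withr::with_seed(seed, gazedecode:::stratified_folds(labels, 10))
    for (cl in 1:8) {
      per_fold <- tabulate(folds[labels == cl], 10)
      expect_lte(max(abs(per_fold - ceiling(sum(labels == cl) / 10))), 1)
    }
  }
})

test_that("decoding is deterministic given the seed", {
  f <- make_features(seed = 4, sep = 0.3)
  expect_identical(crossval_decode(f, seed = 9), crossval_decode(f, seed = 9))
  expect_false(identical(crossval_decode(f, seed = 9)$fold_accuracies,
                         crossval_decode(f, seed = 10)$fold_accuracies))
})

test_that("scaling is fitted on training rows only", {
  f <- make_features(seed = 5)
  labels <- match(f$orientation, sort(unique(f$orientation)))
  folds <- withr::with_seed(1, gazedecode:::stratified_folds(labels, 10))
  tr <- folds != 1
  base <- gazedecode:::col_med_iqr(f$x[tr, ])
  mod <- f$x
  mod[!tr, ] <- mod[!tr, ] * 1000  # corrupt the held-out rows only
  expect_identical(gazedecode:::col_med_iqr(mod[tr, ]), base)
})

test_that("the scaler matches R's median and IQR conventions", {
  x <- matrix(rnorm(500), 100, 5)
  sc <- gazedecode:::col_med_iqr(x)
  expect_equal(sc[1, ], apply(x, 2, median))
  expect_equal(sc[2, ], apply(x, 2, stats::IQR))
})

test_that("the max-margin solver agrees with an independent SVM", {
  # binary problem: same QP as libsvm up to bias regularization
  withr::with_seed(7, {
    X <- matrix(rnorm(200 * 6), 200, 6)
    X[1:100, 1:2] <- X[1:100, 1:2] + 2
    y <- rep(c(1L, 2L), each = 100)
  })
  W <- gazedecode:::ovr_svm_train(X, y, 2L, 0.1, tol = 1e-6,
                                  max_epoch = 20000)
  m <- e1071::svm(X, factor(y), kernel = "linear", cost = 0.1, scale = FALSE)
  w_ref <- c(as.vector(t(m$coefs) %*% m$SV), -m$rho)
  w_mine <- W[, 1]
  # same decision direction ...
  cossim <- sum(w_ref * w_mine) / sqrt(sum(w_ref^2) * sum(w_mine^2))
  expect_gt(cossim, 0.99)
  # ... and matching predictions
  pred <- gazedecode:::ovr_svm_predict(X, W)
  expect_gt(mean(pred == as.integer(predict(m, X))), 0.95)

  # multiclass on separable data: both schemes solve it
  f <- make_features(n_per_class = 20, sep = 5, seed = 8)
  lab <- match(f$orientation, sort(unique(f$orientation)))
  W8 <- gazedecode:::ovr_svm_train(f$x, lab, 8L, 0.1)
  m8 <- e1071::svm(f$x, factor(lab), kernel = "linear", cost = 0.1,
                   scale = FALSE)
  expect_gt(mean(gazedecode:::ovr_svm_predict(f$x, W8) == lab), 0.97)
  expect_gt(mean(predict(m8, f$x) == factor(lab)), 0.97)
})

test_that("permutation test reports the add-one p and percentile rule", {
  f <- make_features(n_per_class = 12, k = 4, sep = 1.2, seed = 11)
  pt <- permutation_test(f, n_perm = 60, seed = 2)
  expect_length(pt$null_accuracies, 60)
  expect_equal(pt$p_value,
               (1 + sum(pt$null_accuracies >= pt$observed)) / 61)
  crit <- sort(pt$null_accuracies)[ceiling(0.95 * 60)]
  expect_identical(pt$significant, pt$observed > crit)
  expect_identical(pt, permutation_test(f, n_perm = 60, seed = 2))
})

test_that("strong signal is detected, and infeasible input degrades safely", {
  f <- make_features(n_per_class = 15, k = 4, sep = 8, seed = 12)
  pt <- permutation_test(f, n_perm = 60, seed = 3)
  expect_true(pt$significant)
  expect_lt(pt$p_value, 0.05)

  small <- make_features(n_per_class = 5, k = 4, seed = 13)
  pt2 <- permutation_test(small, n_perm = 20, seed = 1)
  expect_false(pt2$feasible)
  expect_false(pt2$significant)
})
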