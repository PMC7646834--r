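# SVM k-fold cross-validation, feature ranking and count optimization.

test_that("separable blobs are classified without error for any usual k", {
  blobs <- make_blobs(n_per_class = 12, sep = 10, seed = 2)
  for (k in c(3, 5, 10)) {
    rep <- svm_cv(blobs$x, blobs$labels, cv_config(k = k, seed = 4))
    expect_equal(rep$error_rate, 0)
  }
  # linear kernel too
  rep <- svm_cv(blobs$x, blobs$labels,
                cv_config(k = 5, kernel = "linear", seed = 4))
  expect_equal(rep$error_rate, 0)
})

test_that("error rate is exactly recomputable from stored predictions", {
  blobs <- make_blobs(n_per_class = 8, sep = 2, noise = 2, seed = 6)
  rep <- svm_cv(blobs$x, blobs$labels, cv_config(k = 4, seed = 1))
  expect_identical(rep$error_rate,
                   sum(rep$samples$predicted != rep$samples$truth) /
                     nrow(rep$samples))
})

test_that("fold bookkeeping excludes each fold's own test rows", {
  blobs <- make_blobs(n_per_class = 8, seed = 3)
  rep <- svm_cv(blobs$x, blobs$labels, cv_config(k = 4, seed = 9))
  for (f in 1:4) {
    expect_length(intersect(rep$fold_train_rows[[f]],
                            which(rep$folds == f)), 0)
  }
})

test_that("stratification and fold-count guards fire", {
  blobs <- make_blobs(n_per_class = 4, seed = 5)
  expect_error(svm_cv(blobs$x, blobs$labels, cv_config(k = 6, seed = 1)),
               ">= k samples")
  expect_error(svm_cv(blobs$x, blobs$labels, cv_config(k = 40, seed = 1)),
               "exceeds")
  expect_error(cv_config(k = 1), "k must be")
  expect_error(cv_config(cost = 0), "cost")
})

test_that("patient-grouped folds keep all spots of a patient together", {
  blobs <- make_blobs(n_per_class = 12, seed = 8)
  pats <- rep(sprintf("pt%02d", 1:12), each = 3)
  rep <- svm_cv(blobs$x, blobs$labels,
                cv_config(k = 3, seed = 2, group_by_patient = TRUE),
                patient_ids = pats)
  spread <- tapply(rep$folds, pats, function(f) length(unique(f)))
  expect_true(all(spread == 1))
})

test_that("error-vs-k curves cover the requested grid", {
  blobs <- make_blobs(n_per_class = 10, sep = 10, seed = 1)
  curves <- error_vs_k(blobs$x, blobs$labels, k_values = c(3, 5),
                       kernels = "rbf")
  expect_equal(nrow(curves), 2)
  expect_true(all(curves$error_rate == 0))
})

test_that("low k inflates the error on noisy data (repeated seeds)", {
  blobs <- make_blobs(n_per_class = 10, sep = 2.5, noise = 2, seed = 10)
  errs <- vapply(1:20, function(r) {
    cfg2 <- cv_config(k = 2, kernel = "linear", seed = r)
    cfg10 <- cv_config(k = 10, kernel = "linear", seed = r)
    svm_cv(blobs$x, blobs$labels, cfg2)$error_rate -
      svm_cv(blobs$x, blobs$labels, cfg10)$error_rate
  }, numeric(1))
  expect_gt(mean(errs), 0)
})

test_that("ANOVA feature ranking finds separators and demotes constants", {
  set.seed(5)
  x <- matrix(stats::rnorm(30 * 4), 30)
  y <- rep(tumor_classes(), each = 10)
  x[, 3] <- (y == "RO") * 10 + stats::rnorm(30, 0, 0.1)  # perfect separator
  x[, 4] <- 7                                            # constant
  r <- rank_features_anova(x, y)
  expect_equal(r$order[1], 3)
  expect_equal(r$order[length(r$order)], 4)
  expect_equal(r$F[4], 0)
  expect_error(rank_features_anova(x, rep("RO", 30)), "2 classes")
})

test_that("per-fold ranking differs from global ranking when folds drop the signal", {
  # feature 1 separates classes only through samples 1-3 and 7-9 (F = 10
  # by its half-split structure); feature 2 separates globally but more
  # weakly (diff 1 at sd 0.7 gives F ~ 6). Dropping the carrier samples
  # leaves feature 1 with pure noise, so the subset ranking flips.
  set.seed(1)
  y <- rep(c("RO", "ccRCC"), each = 6)
  x <- cbind(0.01 * stats::rnorm(12), stats::rnorm(12, 0, 0.7))
  x[1:3, 1] <- 5; x[7:9, 1] <- -5
  x[y == "RO", 2] <- x[y == "RO", 2] + 1
  global <- rank_features_anova(x, y)
  sub <- rank_features_anova(x[c(4:6, 10:12), ], y[c(4:6, 10:12)])
  expect_equal(global$order[1], 1)
  expect_equal(sub$order[1], 2)
})

test_that("feature optimization reduces to plain CV at the full feature set", {
  blobs <- make_blobs(n_per_class = 8, sep = 3, noise = 1.5, seed = 12)
  cfg <- cv_config(k = 4, seed = 31)
  fo <- feature_optimize(blobs$x, blobs$labels, cfg,
                         n_grid = c(2, ncol(blobs$x)))
  plain <- svm_cv(blobs$x, blobs$labels, cfg)
  expect_equal(fo$curve$error_rate[fo$curve$n_features == ncol(blobs$x)],
               plain$error_rate)
  expect_error(feature_optimize(blobs$x, blobs$labels, cfg,
                                n_grid = integer(0)), "empty")
  expect_error(feature_optimize(blobs$x, blobs$labels, cfg, n_grid = 99),
               "must lie in")
})

test_that("a table with 10 informative features needs at most 10 for zero error", {
  set.seed(17)
  n_per <- 10; p <- 50
  y <- rep(tumor_classes(), each = n_per)
  zero_err_n <- integer(0); err2 <- numeric(0); err10 <- numeric(0)
  for (s in 1:3) {
    x <- matrix(stats::rnorm(3 * n_per * p), 3 * n_per, p)
    for (k in 1:3) {  # 10 informative: features 1..10, split over classes
      cols <- ((k - 1) * 3 + 1):min(k * 3 + 1, 10)
      x[y == tumor_classes()[k], cols] <-
        x[y == tumor_classes()[k], cols] + 4
    }
    fo <- feature_optimize(x, y, cv_config(k = 5, seed = s),
                           n_grid = c(2, 10, p))
    zero_err_n <- c(zero_err_n, fo$min_zero_error_n)
    err2 <- c(err2, fo$curve$error_rate[1])
    err10 <- c(err10, fo$curve$error_rate[2])
  }
  expect_true(all(zero_err_n <= 10, na.rm = TRUE))
  expect_gt(mean(err2), mean(err10))
})

test_that("radar export orders by class, keeps scores consistent, guards ties", {
  blobs <- make_blobs(n_per_class = 12, sep = 8, seed = 3)
  rep <- svm_cv(blobs$x, blobs$labels, cv_config(k = 3, seed = 2))
  radar <- radar_scores(rep)
  expect_equal(radar$truth, rep(tumor_classes(), each = 12))
  expect_true(all(radar$winner == radar$truth))
  expect_false(any(radar$tie))
  rep$samples <- rep$samples[0, ]
  expect_error(radar_scores(rep), "empty")
})
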