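# PLS-DA fitting, component selection, patient-grouped CV and the
# margin-rule patient call. The toy_cohort() fixture lives in
# helper-fixtures.R.

test_that("PLS-DA self-representation scores the true class near 1", {
  y <- rep(tumor_classes(), each = 5)
  X <- outer(y, tumor_classes(), `==`) * 1
  model <- fit_plsda(X, y, n_components = 2)
  sc <- predict(model, X)
  for (i in seq_along(y)) expect_gte(sc[i, y[i]], 0.99)
})

test_that("full-rank PLS-DA equals ordinary least squares", {
  set.seed(7)
  X <- matrix(stats::rnorm(60), 12, 5)
  y <- rep(tumor_classes(), each = 4)
  model <- fit_plsda(X, y, n_components = 5)
  pls_pred <- predict(model, X)
  Y <- outer(y, model$class_order, `==`) * 1
  ols_pred <- stats::fitted(stats::lm(Y ~ X))
  expect_lt(max(abs(pls_pred - ols_pred)), 1e-6)
})

test_that("successive PLS score vectors are mutually orthogonal", {
  set.seed(8)
  X <- matrix(stats::rnorm(200), 20, 10)
  y <- rep(tumor_classes(), length.out = 20)
  model <- fit_plsda(X, y, n_components = 4)
  G <- crossprod(model$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
})

test_that("PLS-DA input guards fire", {
  X <- matrix(stats::rnorm(20), 10, 2)
  expect_error(fit_plsda(X, rep("ccRCC", 10), 1), "2 classes")
  expect_error(fit_plsda(X, rep(c("ccRCC", "RO"), 5), 5), "n_components")
})

test_that("one-component PLS-DA on univariate two-class data tracks the mean difference", {
  set.seed(3)
  x <- matrix(c(stats::rnorm(10, 0), stats::rnorm(10, 4)), ncol = 1)
  y <- rep(c("RO", "ccRCC"), each = 10)
  model <- fit_plsda(x, y, 1)
  # ccRCC has the larger mean: its coefficient on the feature is positive
  expect_gt(model$regression_coefficients[1, "ccRCC"], 0)
  expect_lt(model$regression_coefficients[1, "RO"], 0)
})

test_that("LOPO CV is patient-grouped, accurate, and hygienic", {
  fm <- toy_cohort(seed = 5)
  cv <- loo_patient_cv(fm, n_components = 3)
  expect_gte(min(cv$per_class_accuracy), 0.9)
  # hygiene: held-out patient's rows never appear in that fold's training
  for (pid in names(cv$fold_train_ids)) {
    held_rows <- fm$row_ids[fm$row_groups$patient_id == pid]
    expect_length(intersect(cv$fold_train_ids[[pid]], held_rows), 0)
  }
  # reported accuracy equals a brute-force recount from stored argmax
  sc <- as.matrix(cv$pixel_scores[, cv$class_order])
  recount <- mean(cv$class_order[max.col(sc, ties.method = "first")] ==
                    cv$pixel_scores$truth)
  expect_identical(cv$overall_accuracy, recount)
})

test_that("LOPO CV cohort guards fire", {
  fm <- toy_cohort(n_patients_per_class = 1)
  expect_error(loo_patient_cv(fm, 2), "fewer than 2 patients")
  two <- toy_cohort(seed = 2)
  keep <- two$row_groups$patient_id %in% c("P01", "P04")
  small <- feature_matrix(two$values[keep, ], two$feature_axis,
                          two$row_ids[keep], two$row_groups[keep, ])
  expect_error(loo_patient_cv(small, 2), "at least 3 patients")
})

test_that("component selection plateaus early on strongly-signed phantoms", {
  fm <- toy_cohort(seed = 11)
  sel <- choose_n_components(fm, max_components = 8)
  expect_lte(sel$n_components, 3)
  expect_gte(sel$accuracy[sel$n_components], max(sel$accuracy) - 0.01)
  # max_components = 1 returns 1
  expect_equal(choose_n_components(fm, max_components = 1)$n_components, 1)
})

test_that("pure-noise features give chance-level component selection", {
  fm <- toy_cohort(seed = 13)
  set.seed(13)
  noise <- fm
  noise$values <- matrix(abs(stats::rnorm(length(fm$values))),
                         nrow(fm$values))
  sel <- choose_n_components(noise, max_components = 5)
  # balanced 3 classes: no c should rise far above the 1/3 base rate
  expect_lt(max(sel$accuracy), 0.6)
})

test_that("patient call applies the margin rule arithmetic", {
  mk <- function(cc, ro, ch) {
    matrix(rep(c(cc, ro, ch), each = 5), ncol = 3,
           dimnames = list(NULL, tumor_classes()))
  }
  a <- patient_call(mk(0.80, 0.30, 0.20))
  expect_equal(a$winner, "ccRCC")
  expect_length(a$ambiguous_with, 0)
  b <- patient_call(mk(0.10, 0.50, 0.47))
  expect_equal(b$winner, "RO")
  expect_equal(b$ambiguous_with, "ChRCC")   # 0.03 < 0.05
  c3 <- patient_call(mk(0.10, 0.50, 0.44))
  expect_equal(c3$winner, "RO")
  expect_length(c3$ambiguous_with, 0)       # 0.06 > 0.05
})

test_that("patient call is scale invariant and guards degenerate input", {
  sc <- matrix(c(0.5, 0.47, 0.1), 7, 3, byrow = TRUE,
               dimnames = list(NULL, tumor_classes()))
  a <- patient_call(sc)
  b <- patient_call(sc * 40)
  expect_equal(a$winner, b$winner)
  expect_equal(a$ambiguous_with, b$ambiguous_with)
  expect_error(patient_call(sc[0, , drop = FALSE]), "no pixels")
  # non-positive winner median: unclassifiable
  neg <- patient_call(-sc)
  expect_true(neg$unclassifiable)
})

test_that("feature ranking surfaces the planted class signatures", {
  fm <- toy_cohort(seed = 21, noise = 0.2)
  model <- fit_plsda(fm$values, fm$row_groups$condition, 3)
  model$feature_axis <- fm$feature_axis
  ranks <- rank_features(model)
  expect_setequal(ranks$ccRCC$feature[1:2], c(723.5, 704.5))
  expect_setequal(ranks$RO$feature[1:2], c(806.5, 1640.0))
  expect_setequal(ranks$ChRCC$feature[1:2], c(1169.5, 1039.5))
})

test_that("negating a feature's intensities flips its coefficient sign", {
  set.seed(2)
  X <- matrix(stats::rnorm(90), 30, 3)
  y <- rep(tumor_classes(), each = 10)
  X[, 1] <- X[, 1] + (y == "ccRCC") * 3
  m1 <- fit_plsda(X, y, 2)
  X2 <- X; X2[, 1] <- -X2[, 1]
  m2 <- fit_plsda(X2, y, 2)
  expect_lt(m1$regression_coefficients[1, "ccRCC"] *
              m2$regression_coefficients[1, "ccRCC"], 0)
})

test_that("PCA scores behave like a mean-centered SVD", {
  line <- cbind(1:10, 2 * (1:10))
  pc <- pca_scores(line, 2)
  expect_equal(pc$explained_variance[1], 1)
  # rotation invariance of the variance spectrum
  set.seed(5)
  X <- matrix(stats::rnorm(80), 20, 4)
  R <- qr.Q(qr(matrix(stats::rnorm(16), 4)))
  expect_equal(pca_scores(X, 3)$explained_variance,
               pca_scores(X %*% R, 3)$explained_variance, tolerance = 1e-9)
  expect_error(pca_scores(matrix(1, 10, 3)), "constant")
})

test_that("phantom pixel PCA separates ccRCC from the rest", {
  fm <- toy_cohort(seed = 31)
  pc <- pca_scores(fm$values, 3)
  cc <- fm$row_groups$condition == "ccRCC"
  centroid_cc <- colMeans(pc$scores[cc, ])
  centroid_rest <- colMeans(pc$scores[!cc, ])
  within_cc <- mean(sqrt(rowSums(sweep(pc$scores[cc, ], 2, centroid_cc)^2)))
  between <- sqrt(sum((centroid_cc - centroid_rest)^2))
  expect_gt(between, within_cc)  # positive silhouette-style separation
})
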