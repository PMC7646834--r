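# SVM classification of extraction-spot proteome profiles with k-fold
# cross-validation, kernel comparison and ranked-feature-count
# optimization. Per-class scores are one-vs-rest decision values; the
# highest-scoring condition classifies a sample.

#' Cross-validation configuration for the proteome classifier
#'
#' @param k number of folds, >= 2.
#' @param kernel `"rbf"` (radial basis function, default) or `"linear"`.
#' @param cost SVM cost penalty (default 10).
#' @param rbf_gamma RBF kernel width; `NULL` (default) computes
#'   `1 / (n_features * var(training values))` per training fold.
#' @param seed fold shuffling seed.
#' @param stratified stratify folds by class (default TRUE).
#' @param group_by_patient keep all of a patient's extraction spots in
#'   one fold (recommended against patient-level leakage; default FALSE,
#'   plain sample-level folds).
#' @return object of class `cv_config`.
#' @export
cv_config <- function(k = 5, kernel = c("rbf", "linear"), cost = 10,
                      rbf_gamma = NULL, seed = 1, stratified = TRUE,
                      group_by_patient = FALSE) {
  if (!is_count(k, 2)) stopf("k must be an integer >= 2")
  if (cost <= 0) stopf("cost must be > 0")
  if (!is.null(rbf_gamma) && rbf_gamma <= 0) stopf("rbf_gamma must be > 0")
  structure(
    list(k = k, kernel = match.arg(kernel), cost = cost,
         rbf_gamma = rbf_gamma, seed = as.integer(seed),
         stratified = stratified, group_by_patient = group_by_patient),
    class = "cv_config"
  )
}

# Seeded fold assignment; stratified by class, optionally grouping all
# samples of a patient into one fold.
make_folds <- function(labels, config, patient_ids = NULL) {
  n <- length(labels)
  if (config$k > n) stopf("k (%d) exceeds the sample count (%d)", config$k, n)
  with_seed(derive_seed(config$seed, "folds"), {
    folds <- integer(n)
    if (config$group_by_patient) {
      if (is.null(patient_ids)) stopf("patient-grouped folds need patient ids")
      map <- unique(data.frame(patient = patient_ids, label = labels,
                               stringsAsFactors = FALSE))
      pf <- integer(nrow(map))
      if (config$stratified) {
        for (cls in unique(map$label)) {
          idx <- sample(which(map$label == cls))
          pf[idx] <- rep(seq_len(config$k), length.out = length(idx))
        }
      } else {
        pf[sample(nrow(map))] <- rep(seq_len(config$k), length.out = nrow(map))
      }
      folds <- pf[match(patient_ids, map$patient)]
    } else if (config$stratified) {
      counts <- tabulate(factor(labels))
      if (any(counts < config$k)) {
        stopf("stratified folds need >= k samples in every class")
      }
      for (cls in unique(labels)) {
        idx <- sample(which(labels == cls))
        folds[idx] <- rep(seq_len(config$k), length.out = length(idx))
      }
    } else {
      folds[sample(n)] <- rep(seq_len(config$k), length.out = n)
    }
    folds
  })
}

# One-vs-rest multiclass SVM: fit one binary machine per class on the
# training data, return decision-value scores for the test rows.
ovr_svm_scores <- function(train_x, train_y, test_x, config) {
  classes <- plsda_class_order(train_y)
  gamma <- config$rbf_gamma
  if (is.null(gamma) && config$kernel == "rbf") {
    v <- stats::var(as.vector(train_x))
    gamma <- if (v > 0) 1 / (ncol(train_x) * v) else 1 / ncol(train_x)
  }
  scores <- matrix(0, nrow(test_x), length(classes),
                   dimnames = list(NULL, classes))
  for (cls in classes) {
    ybin <- factor(ifelse(train_y == cls, cls, ".rest"),
                   levels = c(cls, ".rest"))
    args <- list(x = train_x, y = ybin,
                 kernel = if (config$kernel == "rbf") "radial" else "linear",
                 cost = config$cost, scale = FALSE)
    if (config$kernel == "rbf") args$gamma <- gamma
    m <- do.call(e1071::svm, args)
    dv <- attr(stats::predict(m, test_x, decision.values = TRUE),
               "decision.values")
    # decision values are signed toward the class named first in the
    # "A/B" column label (training-data order, not factor level order)
    first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
    scores[, cls] <- if (first == cls) dv[, 1] else -dv[, 1]
  }
  scores
}

#' k-fold cross-validated SVM classification
#'
#' Samples are shuffled into k (stratified) folds; per fold a multiclass
#' one-vs-rest SVM is trained on the other k-1 folds and the held-out
#' samples receive one decision score per class; the highest-scoring
#' condition classifies the sample. Feature standardization is fitted on
#' the training fold only.
#'
#' @param x samples x features numeric matrix (or [feature_matrix()]).
#' @param labels per-sample class labels.
#' @param config a [cv_config()].
#' @param patient_ids per-sample patient ids (needed for patient-grouped
#'   folds).
#' @return object of class `cv_report`: `samples` data.frame (truth,
#'   predicted, per-class scores, fold), `error_rate`
#'   (misclassified / n, exact), `class_order`, `folds`, config echo.
#' @export
svm_cv <- function(x, labels, config = cv_config(), patient_ids = NULL) {
  xv <- as_values(x)
  labels <- as.character(labels)
  if (nrow(xv) != length(labels)) stopf("one label per sample required")
  folds <- make_folds(labels, config, patient_ids)
  classes <- plsda_class_order(labels)
  scores <- matrix(NA_real_, nrow(xv), length(classes),
                   dimnames = list(NULL, classes))
  fold_train_rows <- vector("list", config$k)
  for (f in sort(unique(folds))) {
    train <- folds != f
    lost <- setdiff(classes, unique(labels[train]))
    if (length(lost) > 0) {
      stopf("class %s is absent from the training folds for fold %d",
            lost[1], f)
    }
    mu <- colMeans(xv[train, , drop = FALSE])
    sd_ <- apply(xv[train, , drop = FALSE], 2, stats::sd)
    sd_[sd_ == 0] <- 1
    scale_rows <- function(m) sweep(sweep(m, 2, mu), 2, sd_, `/`)
    scores[!train, ] <- ovr_svm_scores(
      scale_rows(xv[train, , drop = FALSE]), labels[train],
      scale_rows(xv[!train, , drop = FALSE]), config
    )
    fold_train_rows[[f]] <- which(train)
  }
  predicted <- classes[max.col(scores, ties.method = "first")]
  tie <- apply(scores, 1, function(s) sum(s == max(s)) > 1)
  samples <- data.frame(
    sample_id = if (!is.null(rownames(xv))) rownames(xv) else seq_along(labels),
    truth = labels, predicted = predicted, fold = folds,
    score_tie = tie, scores,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  if (!is.null(patient_ids)) samples$patient_id <- patient_ids
  structure(
    list(samples = samples,
         error_rate = sum(predicted != labels) / length(labels),
         class_order = classes, folds = folds, config = config,
         fold_train_rows = fold_train_rows),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d samples, k=%d %s kernel, error rate %.2f%%\n",
              nrow(x$samples), x$config$k, x$config$kernel,
              100 * x$error_rate))
  invisible(x)
}

#' Cross-validation error over a grid of k values and kernels
#'
#' @param x samples x features matrix.
#' @param labels per-sample classes.
#' @param k_values fold counts to test.
#' @param kernels kernel names (subset of `"rbf"`, `"linear"`).
#' @param n_rep repeated-seed replicates per point (default 1; more
#'   reports mean and SD over fold reshuffles).
#' @param seed base seed.
#' @param ... further [cv_config()] fields.
#' @return data.frame with columns `k`, `kernel`, `error_rate`,
#'   `error_sd`.
#' @export
error_vs_k <- function(x, labels, k_values = 2:10,
                       kernels = c("rbf", "linear"), n_rep = 1, seed = 1,
                       ...) {
  grid <- expand.grid(k = k_values, kernel = kernels,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    errs <- vapply(seq_len(n_rep), function(r) {
      cfg <- cv_config(k = grid$k[i], kernel = grid$kernel[i],
                       seed = derive_seed(seed, "rep", r), ...)
      svm_cv(x, labels, cfg)$error_rate
    }, numeric(1))
    data.frame(k = grid$k[i], kernel = grid$kernel[i],
               error_rate = mean(errs),
               error_sd = if (n_rep > 1) stats::sd(errs) else NA_real_)
  })
  do.call(rbind, res)
}

#' Rank features by one-way ANOVA F statistic
#'
#' Between/within variance ratio per feature, computed on training data
#' only (call inside each CV fold). Constant features get F = 0 and rank
#' last.
#'
#' @param x training samples x features matrix.
#' @param labels training class labels (>= 2 classes).
#' @return list with `order` (feature indices, best first) and `F`
#'   (per-feature statistics).
#' @export
rank_features_anova <- function(x, labels) {
  xv <- as_values(x)
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) < 2) stopf("feature ranking requires >= 2 classes")
  n <- nrow(xv)
  K <- length(classes)
  grand <- colMeans(xv)
  ssb <- numeric(ncol(xv))
  ssw <- numeric(ncol(xv))
  for (cls in classes) {
    idx <- labels == cls
    nk <- sum(idx)
    mk <- colMeans(xv[idx, , drop = FALSE])
    ssb <- ssb + nk * (mk - grand)^2
    ssw <- ssw + colSums(sweep(xv[idx, , drop = FALSE], 2, mk)^2)
  }
  f <- ifelse(ssw > 0, (ssb / (K - 1)) / (ssw / (n - K)),
              ifelse(ssb > 0, Inf, 0))
  list(order = order(-f), F = f)
}

#' Error rate as a function of the number of top-ranked features
#'
#' For every n in the grid, runs the k-fold CV using only the top-n
#' ANOVA-ranked features, with the ranking recomputed inside each
#' training fold (no test leakage). Fold assignments are identical
#' across the grid and identical to [svm_cv()] under the same config, so
#' the full-feature point reproduces the plain CV error exactly.
#'
#' @param x samples x features matrix.
#' @param labels per-sample classes.
#' @param config a [cv_config()] (study setting: k = 5, RBF kernel).
#' @param n_grid feature counts to test (default: a log-spaced grid up
#'   to all features).
#' @param patient_ids optional patient ids for grouped folds.
#' @return object of class `feature_curve`: data.frame
#'   (`n_features`, `error_rate`), plus `min_zero_error_n` (smallest n
#'   with zero error; NA when none).
#' @export
feature_optimize <- function(x, labels, config = cv_config(),
                             n_grid = NULL, patient_ids = NULL) {
  xv <- as_values(x)
  labels <- as.character(labels)
  p <- ncol(xv)
  if (is.null(n_grid)) {
    n_grid <- sort(unique(pmin(p, c(1, 2, 4, 8, 15, 21, 30, 50, 100, 200, p))))
  }
  if (length(n_grid) == 0) stopf("empty feature-count grid")
  if (any(n_grid < 1 | n_grid > p)) stopf("n_grid must lie in 1..%d", p)
  folds <- make_folds(labels, config, patient_ids)
  classes <- plsda_class_order(labels)

  errors <- vapply(sort(n_grid), function(nf) {
    predicted <- character(length(labels))
    for (f in sort(unique(folds))) {
      train <- folds != f
      ranking <- rank_features_anova(xv[train, , drop = FALSE], labels[train])
      feat <- ranking$order[seq_len(nf)]
      mu <- colMeans(xv[train, feat, drop = FALSE])
      sd_ <- apply(xv[train, feat, drop = FALSE], 2, stats::sd)
      sd_[sd_ == 0] <- 1
      scale_rows <- function(m) sweep(sweep(m, 2, mu), 2, sd_, `/`)
      sc <- ovr_svm_scores(
        scale_rows(xv[train, feat, drop = FALSE]), labels[train],
        scale_rows(xv[!train, feat, drop = FALSE]), config
      )
      predicted[!train] <- classes[max.col(sc, ties.method = "first")]
    }
    mean(predicted != labels)
  }, numeric(1))

  curve <- data.frame(n_features = sort(n_grid), error_rate = errors)
  zero <- curve$n_features[curve$error_rate == 0]
  structure(
    list(curve = curve,
         min_zero_error_n = if (length(zero) > 0) min(zero) else NA_integer_,
         config = config),
    class = "feature_curve"
  )
}

#' @export
print.feature_curve <- function(x, ...) {
  cat(sprintf("<feature_curve> %d grid points; minimal zero-error n = %s\n",
              nrow(x$curve),
              if (is.na(x$min_zero_error_n)) "none" else x$min_zero_error_n))
  invisible(x)
}

#' Per-sample score triples for radar-plot export
#'
#' Orders the CV report's samples by true class (class order) then
#' patient/sample id and re-derives the winner from the scores,
#' asserting consistency with the report's stored predictions. Ties are
#' broken by class order and flagged.
#'
#' @param report a [svm_cv()] report.
#' @return data.frame with sample id, truth, the three class scores,
#'   `winner` and `tie` flag.
#' @export
radar_scores <- function(report) {
  s <- report$samples
  if (is.null(s) || nrow(s) == 0) stopf("empty CV report")
  classes <- report$class_order
  ord <- order(match(s$truth, classes),
               if (!is.null(s$patient_id)) s$patient_id else s$sample_id,
               s$sample_id)
  s <- s[ord, , drop = FALSE]
  sc <- as.matrix(s[, classes, drop = FALSE])
  winner <- classes[max.col(sc, ties.method = "first")]
  if (!all(winner == s$predicted)) {
    stopf("stored predictions disagree with the recomputed argmax")
  }
  data.frame(sample_id = s$sample_id, truth = s$truth,
             sc, winner = winner, tie = s$score_tie,
             stringsAsFactors = FALSE, check.names = FALSE)
}
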