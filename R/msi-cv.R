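# Leave-one-patient-out cross-validation of the pixel classifier and the
# patient-level call with the 10% margin rule.

# Validate that a labeled cohort supports LOPO CV; returns the patient ->
# class map.
lopo_cohort <- function(patient_ids, labels) {
  patient_ids <- as.character(patient_ids)
  labels <- as.character(labels)
  map <- unique(data.frame(patient_id = patient_ids, label = labels,
                           stringsAsFactors = FALSE))
  if (anyDuplicated(map$patient_id)) {
    stopf("a patient carries more than one pathology label")
  }
  if (nrow(map) < 3) stopf("leave-one-patient-out CV needs at least 3 patients")
  counts <- table(map$label)
  short <- names(counts)[counts < 2]
  if (length(short) > 0) {
    stopf("class %s has fewer than 2 patients; a fold would lose the class",
          short[1])
  }
  map
}

#' Leave-one-patient-out cross-validation of PLS-DA pixel classification
#'
#' One model per patient, trained on all other patients' pixels; every
#' pixel of the held-out patient receives one continuous score per class.
#' Patient-pixel grouping is mandatory: pixels of the held-out patient
#' never appear in training (the returned fold bookkeeping makes this
#' assertable).
#'
#' @param X a [feature_matrix()] whose `row_groups` carry `patient_id`
#'   and `condition` per pixel.
#' @param n_components PLS components per fold model.
#' @return object of class `lopo_cv_result`: `pixel_scores` (data.frame
#'   with row id, patient, truth, per-class scores, predicted class),
#'   `per_class_accuracy`, `overall_accuracy` (pixel-level),
#'   `class_order`, and `fold_train_ids` (row ids used to train each
#'   fold's model).
#' @export
loo_patient_cv <- function(X, n_components) {
  groups <- X$row_groups
  if (is.null(groups) || !all(c("patient_id", "condition") %in% names(groups))) {
    stopf("X must carry patient_id and condition row groups")
  }
  map <- lopo_cohort(groups$patient_id, groups$condition)
  classes <- plsda_class_order(map$label)

  all_scores <- vector("list", nrow(map))
  fold_train_ids <- vector("list", nrow(map))
  names(fold_train_ids) <- map$patient_id
  for (i in seq_len(nrow(map))) {
    held <- map$patient_id[i]
    train <- groups$patient_id != held
    train_classes <- unique(groups$condition[train])
    lost <- setdiff(map$label, train_classes)
    if (length(lost) > 0) {
      stopf("training fold for patient %s loses class %s", held, lost[1])
    }
    model <- fit_plsda(X$values[train, , drop = FALSE],
                       groups$condition[train], n_components)
    test <- !train
    sc <- predict(model, X$values[test, , drop = FALSE])
    sc <- sc[, classes, drop = FALSE]
    all_scores[[i]] <- data.frame(
      row_id = X$row_ids[test],
      patient_id = held,
      truth = groups$condition[test],
      sc,
      predicted = classes[max.col(sc, ties.method = "first")],
      stringsAsFactors = FALSE, check.names = FALSE
    )
    fold_train_ids[[i]] <- X$row_ids[train]
  }
  pixel_scores <- do.call(rbind, all_scores)
  rownames(pixel_scores) <- NULL
  correct <- pixel_scores$predicted == pixel_scores$truth
  per_class <- vapply(classes, function(cls) {
    sel <- pixel_scores$truth == cls
    mean(correct[sel])
  }, numeric(1))
  structure(
    list(pixel_scores = pixel_scores,
         per_class_accuracy = per_class,
         overall_accuracy = mean(correct),
         class_order = classes,
         n_components = n_components,
         fold_train_ids = fold_train_ids),
    class = "lopo_cv_result"
  )
}

#' @export
print.lopo_cv_result <- function(x, ...) {
  cat(sprintf(
    "<lopo_cv_result> %d pixels, %d patients, pixel accuracy %.1f%% (%s)\n",
    nrow(x$pixel_scores), length(x$fold_train_ids),
    100 * x$overall_accuracy,
    paste(sprintf("%s %.0f%%", names(x$per_class_accuracy),
                  100 * x$per_class_accuracy), collapse = ", ")
  ))
  invisible(x)
}

#' Choose the PLS component count by leave-one-patient-out accuracy
#'
#' Sweeps c = 1..max_components, scoring each truncation of a single
#' per-fold NIPALS fit (the coefficient path makes the sweep cheap), and
#' returns the c maximizing mean pixel-level accuracy; ties go to the
#' smallest c.
#'
#' @param X a [feature_matrix()] with `patient_id`/`condition` groups.
#' @param max_components largest component count to test (default 34).
#' @return list with `n_components` (the optimum), `accuracy` (per-c mean
#'   pixel accuracy) and `tested` (the c grid).
#' @export
choose_n_components <- function(X, max_components = 34) {
  if (!is_count(max_components, 1)) stopf("max_components must be >= 1")
  groups <- X$row_groups
  map <- lopo_cohort(groups$patient_id, groups$condition)
  classes <- plsda_class_order(map$label)
  max_c <- min(max_components, nrow(X$values) - 1, ncol(X$values))

  acc <- matrix(NA_real_, nrow(map), max_c)
  for (i in seq_len(nrow(map))) {
    held <- map$patient_id[i]
    train <- groups$patient_id != held
    model <- fit_plsda(X$values[train, , drop = FALSE],
                       groups$condition[train], max_c)
    test <- !train
    truth <- groups$condition[test]
    for (a in seq_len(model$n_components)) {
      sc <- predict(model, X$values[test, , drop = FALSE], n_components = a)
      sc <- sc[, classes, drop = FALSE]
      pred <- classes[max.col(sc, ties.method = "first")]
      acc[i, a] <- mean(pred == truth)
    }
  }
  mean_acc <- colMeans(acc)
  usable <- which(!is.na(mean_acc))
  best <- usable[which.max(mean_acc[usable])]  # which.max takes first = smallest c
  list(n_components = best, accuracy = mean_acc, tested = seq_len(max_c))
}

#' Patient-level call from pixel scores with the margin rule
#'
#' The patient's score per class is the median over their pixels; the
#' winner is the class with the highest median. Any other class whose
#' median lies within `margin_fraction` of the winner's median (relative
#' to the absolute winner median) is considered indistinguishable and
#' joins the ambiguity set. A non-positive winner median makes the call
#' unclassifiable.
#'
#' @param pixel_scores data.frame of one patient's pixel scores with one
#'   column per class (as produced by [loo_patient_cv()]), or a numeric
#'   matrix with class columns.
#' @param classes class column names (default [tumor_classes()]
#'   restricted to present columns).
#' @param margin_fraction the margin rule constant (default 0.10).
#' @param patient_id optional identifier stored in the call.
#' @return object of class `patient_call`: `median_scores`, `winner`,
#'   `ambiguous_with`, `unclassifiable`, `margin_fraction`.
#' @export
patient_call <- function(pixel_scores, classes = NULL, margin_fraction = 0.10,
                         patient_id = NULL) {
  if (margin_fraction <= 0 || margin_fraction >= 1) {
    stopf("margin_fraction must be in (0, 1)")
  }
  scores <- if (is.data.frame(pixel_scores)) {
    if (is.null(classes)) {
      classes <- intersect(tumor_classes(), names(pixel_scores))
      if (length(classes) == 0) stopf("no class score columns found")
    }
    as.matrix(pixel_scores[, classes, drop = FALSE])
  } else {
    m <- as.matrix(pixel_scores)
    if (is.null(classes)) classes <- colnames(m)
    m[, classes, drop = FALSE]
  }
  if (nrow(scores) == 0) stopf("no pixels: cannot call a patient")
  med <- apply(scores, 2, stats::median)
  names(med) <- classes
  winner <- classes[which.max(med)]  # first = class-order tie-break
  unclassifiable <- med[winner] <= 0
  ambiguous <- character(0)
  if (!unclassifiable) {
    others <- setdiff(classes, winner)
    gap <- med[winner] - med[others]
    ambiguous <- others[gap < margin_fraction * abs(med[winner])]
  }
  structure(
    list(patient_id = patient_id, median_scores = med, winner = winner,
         ambiguous_with = ambiguous, unclassifiable = unclassifiable,
         margin_fraction = margin_fraction),
    class = "patient_call"
  )
}

#' @export
print.patient_call <- function(x, ...) {
  cat(sprintf(
    "<patient_call>%s %s%s%s (%s)\n",
    if (!is.null(x$patient_id)) paste0(" ", x$patient_id) else "",
    x$winner,
    if (length(x$ambiguous_with) > 0) {
      paste0("/", paste(x$ambiguous_with, collapse = "/"))
    } else "",
    if (x$unclassifiable) " [unclassifiable]" else "",
    paste(sprintf("%s=%.3f", names(x$median_scores), x$median_scores),
          collapse = ", ")
  ))
  invisible(x)
}

#' Patient calls for every patient of a cross-validation result
#'
#' @param cv a [loo_patient_cv()] result.
#' @param margin_fraction margin rule constant (default 0.10).
#' @return named list of [patient_call()]s.
#' @export
patient_calls_from_cv <- function(cv, margin_fraction = 0.10) {
  patients <- unique(cv$pixel_scores$patient_id)
  calls <- lapply(patients, function(pid) {
    patient_call(cv$pixel_scores[cv$pixel_scores$patient_id == pid, ],
                 classes = cv$class_order,
                 margin_fraction = margin_fraction, patient_id = pid)
  })
  names(calls) <- patients
  calls
}
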