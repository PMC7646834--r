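# PLS-DA: partial least squares regression (PLS2, NIPALS) on one-hot
# class indicators, used as a multiclass classifier. Prediction yields one
# continuous score per class per row; argmax is the class call.

as_values <- function(X) {
  if (inherits(X, "feature_matrix")) X$values else as.matrix(X)
}

as_axis <- function(X) {
  if (inherits(X, "feature_matrix")) X$feature_axis else colnames(as.matrix(X))
}

plsda_class_order <- function(labels) {
  present <- unique(as.character(labels))
  known <- tumor_classes()[tumor_classes() %in% present]
  c(known, setdiff(present, known))
}

#' Fit a PLS-DA model
#'
#' Labels are one-hot encoded; X and Y are mean-centered; components are
#' extracted by the iterative NIPALS PLS2 procedure. At
#' `n_components = rank(X)` the fitted predictions coincide with ordinary
#' least squares regression of the indicator matrix on X.
#'
#' @param X a [feature_matrix()] or numeric matrix (rows = pixels).
#' @param labels class label per row; at least 2 distinct classes.
#' @param n_components number of latent components, between 1 and
#'   `min(nrow(X) - 1, ncol(X))`.
#' @return object of class `plsda_model`: weights `W`, loadings `P`,
#'   y-loadings `Q`, scores `T`, x/y means, per-component and final
#'   regression coefficients, `class_order`.
#' @export
fit_plsda <- function(X, labels, n_components) {
  Xv <- as_values(X)
  labels <- as.character(labels)
  classes <- plsda_class_order(labels)
  if (length(classes) < 2) stopf("PLS-DA requires at least 2 classes")
  max_c <- min(nrow(Xv) - 1, ncol(Xv))
  if (!is_count(n_components, 1) || n_components > max_c) {
    stopf("n_components must be in 1..%d", max_c)
  }
  Y <- outer(labels, classes, `==`) * 1
  colnames(Y) <- classes

  x_mean <- colMeans(Xv)
  y_mean <- colMeans(Y)
  E <- sweep(Xv, 2, x_mean)
  F_ <- sweep(Y, 2, y_mean)

  p <- ncol(E); q <- ncol(F_)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Q <- matrix(0, q, n_components)
  Tm <- matrix(0, nrow(E), n_components)
  a_used <- 0
  for (a in seq_len(n_components)) {
    u <- F_[, which.max(apply(F_, 2, stats::var))]
    if (sum(u^2) < 1e-30 || sum(E^2) < 1e-30) break
    t_old <- rep(Inf, nrow(E))
    for (it in seq_len(500)) {
      w <- crossprod(E, u)
      wn <- sqrt(sum(w^2))
      if (wn < 1e-30) break
      w <- w / wn
      tt <- E %*% w
      qv <- crossprod(F_, tt) / sum(tt^2)
      u <- F_ %*% qv / sum(qv^2)
      if (sqrt(sum((tt - t_old)^2)) < 1e-12 * max(1, sqrt(sum(tt^2)))) break
      t_old <- tt
    }
    if (wn < 1e-30) break
    pv <- crossprod(E, tt) / sum(tt^2)
    E <- E - tt %*% t(pv)
    F_ <- F_ - tt %*% t(qv)
    W[, a] <- w; P[, a] <- pv; Q[, a] <- qv; Tm[, a] <- tt
    a_used <- a
  }
  if (a_used == 0) stopf("no PLS component could be extracted (constant X?)")
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  Q <- Q[, seq_len(a_used), drop = FALSE]
  Tm <- Tm[, seq_len(a_used), drop = FALSE]

  model <- structure(
    list(n_components = a_used, x_mean = x_mean, y_mean = y_mean,
         weights = W, loadings = P, y_loadings = Q, scores = Tm,
         class_order = classes, feature_axis = as_axis(X)),
    class = "plsda_model"
  )
  model$regression_coefficients <- plsda_coefficients(model, a_used)
  model
}

#' Regression coefficients of a truncated PLS-DA model
#'
#' `B_a = W_a (P_a' W_a)^{-1} Q_a'` using the first `a` components, so a
#' single fit yields the whole component path (used by the component
#' sweep in [choose_n_components()]).
#'
#' @param model a [fit_plsda()] model.
#' @param n_components number of leading components to use.
#' @return features x classes coefficient matrix.
#' @export
plsda_coefficients <- function(model, n_components = model$n_components) {
  a <- n_components
  if (!is_count(a, 1) || a > model$n_components) {
    stopf("n_components must be in 1..%d", model$n_components)
  }
  W <- model$weights[, seq_len(a), drop = FALSE]
  P <- model$loadings[, seq_len(a), drop = FALSE]
  Q <- model$y_loadings[, seq_len(a), drop = FALSE]
  B <- W %*% solve(crossprod(P, W), t(Q))
  dimnames(B) <- list(NULL, model$class_order)
  B
}

#' Predict class scores with a PLS-DA model
#'
#' @param object a `plsda_model`.
#' @param newdata [feature_matrix()] or matrix with the training feature
#'   axis.
#' @param n_components number of components to use (default: all fitted).
#' @param ... unused.
#' @return rows x classes matrix of continuous scores; argmax per row is
#'   the class call.
#' @export
predict.plsda_model <- function(object, newdata,
                                n_components = object$n_components, ...) {
  Xv <- as_values(newdata)
  B <- if (n_components == object$n_components) {
    object$regression_coefficients
  } else {
    plsda_coefficients(object, n_components)
  }
  scores <- sweep(Xv, 2, object$x_mean) %*% B
  sweep(scores, 2, object$y_mean, `+`)
}

#' Rank features by signed PLS-DA coefficient per class
#'
#' A positive coefficient marks presence or higher abundance of the
#' feature in that class; ranking is by descending signed coefficient
#' with a stable sort (ties keep feature-axis order).
#'
#' @param model a fitted `plsda_model`.
#' @return named list (per class) of data.frames with columns `feature`
#'   and `coefficient`, sorted descending.
#' @export
rank_features <- function(model) {
  B <- model$regression_coefficients
  axis <- model$feature_axis
  if (is.null(axis)) axis <- seq_len(nrow(B))
  out <- lapply(model$class_order, function(cls) {
    ord <- order(-B[, cls])  # stable: ties keep original order
    data.frame(feature = axis[ord], coefficient = B[ord, cls])
  })
  names(out) <- model$class_order
  out
}

#' PCA scores of pixel or sample data
#'
#' Mean-centered singular value decomposition; component variances are
#' non-increasing. Used for the initial variance/similarity survey of an
#' image or proteome sample set.
#'
#' @param X [feature_matrix()] or numeric matrix.
#' @param n_components number of components to return (default 3).
#' @return list with `scores` (rows x components), `explained_variance`
#'   (fraction per component over all components) and `sdev`.
#' @export
pca_scores <- function(X, n_components = 3) {
  Xv <- as_values(X)
  if (nrow(Xv) <= n_components) stopf("need more rows than components")
  total_var <- sum(apply(Xv, 2, stats::var))
  if (total_var < 1e-30) stopf("constant matrix has no principal components")
  pc <- stats::prcomp(Xv, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained_variance = pc$sdev^2 / sum(pc$sdev^2),
       sdev = pc$sdev)
}
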