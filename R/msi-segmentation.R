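# Spatially-aware shrunken-centroid segmentation.
#
# Iterative algorithm: (1) k-means initialization on the features;
# (2) per cluster k and feature j, mean x_kj, pooled within-cluster SD
# s_j with stabilizer s0 = median(s_j), and shrunken statistic
# d_kj = (x_kj - x_j) / (m_k (s_j + s0)), m_k = sqrt(1/n_k - 1/n),
# soft-thresholded at s; shrunken centroid
# x'_kj = x_j + m_k (s_j + s0) d'_kj; (3) each pixel is reassigned to the
# cluster minimizing its spatially smoothed standardized distance, where
# the pixel's distance is a weighted average over its Chebyshev radius-r
# neighborhood with Gaussian spatial weights, optionally multiplied by
# adaptive similarity weights; (4) empty clusters are dropped; iterate to
# label convergence. Larger shrinkage s drives cluster centroids toward
# the global mean, merging clusters and selecting the features that
# genuinely separate regions.

#' Parameters for spatial shrunken centroid segmentation
#'
#' @param k_init maximum (initial) number of clusters, >= 1.
#' @param r neighborhood radius in pixels (Chebyshev metric), >= 0;
#'   r = 0 disables spatial smoothing.
#' @param s shrinkage threshold, >= 0; s = 0 disables shrinkage.
#' @param max_iter iteration cap.
#' @param weights `"adaptive"` (Gaussian x similarity, default) or
#'   `"gaussian"` (spatial only).
#' @param seed seed for the k-means initialization.
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(k_init = 8, r = 1, s = 0, max_iter = 20,
                                weights = c("adaptive", "gaussian"),
                                seed = 1) {
  if (!is_count(k_init, 1)) stopf("k_init must be >= 1")
  if (r < 0 || s < 0) stopf("r and s must be >= 0")
  structure(
    list(k_init = k_init, r = r, s = s, max_iter = max_iter,
         weights = match.arg(weights), seed = as.integer(seed)),
    class = "segmentation_params"
  )
}

# Precompute neighbor index lists within Chebyshev radius r, plus the
# Gaussian spatial weight of each neighbor offset (sd = r/2).
neighbor_lists <- function(coords, r) {
  n <- nrow(coords)
  if (r == 0) {
    return(lapply(seq_len(n), function(i) list(idx = i, alpha = 1)))
  }
  key <- paste(coords$x, coords$y)
  lookup <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(key[i], i, envir = lookup)
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  sigma <- max(r / 2, 0.5)
  alpha0 <- exp(-(offs$dx^2 + offs$dy^2) / (2 * sigma^2))
  lapply(seq_len(n), function(i) {
    nk <- paste(coords$x[i] + offs$dx, coords$y[i] + offs$dy)
    hit <- vapply(nk, function(k) {
      if (exists(k, envir = lookup, inherits = FALSE)) {
        get(k, envir = lookup)
      } else NA_integer_
    }, integer(1), USE.NAMES = FALSE)
    ok <- !is.na(hit)
    list(idx = hit[ok], alpha = alpha0[ok])
  })
}

#' Spatial shrunken centroid clustering of MSI pixel data
#'
#' Unsupervised segmentation of an image into histo-molecular clusters
#' (tumor, stroma, background, ...). See the algorithm sketch in the
#' source header; deterministic given `params$seed`.
#'
#' @param matrix a [feature_matrix()] of pixel spectra features.
#' @param coords data.frame (`x`, `y`) in 1-1 correspondence with the
#'   matrix rows; defaults to the matrix's own row groups.
#' @param params a [segmentation_params()].
#' @return object of class `segmentation_result`: `labels` (per-pixel
#'   cluster ids, contiguous from 1), `centroids` and `tstats`
#'   (cluster x feature), `n_iterations`, `objective` (per-iteration
#'   smoothed distance sums) and the parameter echo.
#' @export
spatial_shrunken_centroids <- function(matrix, coords = NULL, params) {
  X <- matrix$values
  if (is.null(coords)) coords <- matrix$row_groups[, c("x", "y")]
  coords <- as.data.frame(coords)
  n <- nrow(X)
  if (nrow(coords) != n) stopf("coords must correspond 1-1 to matrix rows")
  if (any(!is.finite(X))) stopf("non-finite feature values")
  if (params$k_init > n) stopf("k_init (%d) exceeds the pixel count (%d)",
                               params$k_init, n)
  p <- ncol(X)

  n_distinct <- nrow(unique(X))
  labels <- with_seed(params$seed, {
    stats::kmeans(X, centers = min(params$k_init, n, n_distinct),
                  nstart = 3, iter.max = 50)$cluster
  })

  nb <- neighbor_lists(coords, params$r)
  global_mean <- colMeans(X)
  objective <- numeric(0)

  for (iter in seq_len(params$max_iter)) {
    ks <- sort(unique(labels))
    K <- length(ks)
    labels <- match(labels, ks)  # contiguous ids
    nk <- tabulate(labels, K)

    centroids <- matrix(0, K, p)
    for (k in seq_len(K)) {
      centroids[k, ] <- colMeans(X[labels == k, , drop = FALSE])
    }
    # pooled within-cluster SD per feature, + stabilizer
    ss <- numeric(p)
    for (k in seq_len(K)) {
      d <- sweep(X[labels == k, , drop = FALSE], 2, centroids[k, ])
      ss <- ss + colSums(d^2)
    }
    sj <- sqrt(ss / max(n - K, 1))
    s0 <- stats::median(sj)
    scale_j <- sj + s0
    if (all(scale_j == 0)) scale_j <- rep(1, p)

    mk <- sqrt(pmax(1 / nk - 1 / n, 0))
    mk[mk == 0] <- 1e-12
    dkj <- sweep(centroids, 2, global_mean) /
      (mk %o% scale_j)
    dkj_shrunk <- sign(dkj) * pmax(abs(dkj) - params$s, 0)
    shrunk_centroids <- sweep((mk %o% scale_j) * dkj_shrunk, 2, global_mean, `+`)

    # standardized squared distance of every pixel to every shrunken centroid
    Xs <- sweep(X, 2, scale_j, `/`)
    Cs <- sweep(shrunk_centroids, 2, scale_j, `/`)
    dist2 <- outer(rowSums(Xs^2), rep(1, K)) - 2 * Xs %*% t(Cs) +
      outer(rep(1, n), rowSums(Cs^2))
    dist2[dist2 < 0] <- 0

    # spatial smoothing of the distances over each pixel's neighborhood
    if (params$r > 0) {
      smoothed <- dist2
      for (i in seq_len(n)) {
        idx <- nb[[i]]$idx
        w <- nb[[i]]$alpha
        if (params$weights == "adaptive" && length(idx) > 1) {
          dd <- sweep(X[idx, , drop = FALSE], 2, X[i, ])
          d2 <- rowSums(dd^2)
          sig2 <- mean(d2)
          beta <- if (sig2 > 0) exp(-d2 / (2 * sig2)) else rep(1, length(idx))
          w <- w * beta
        }
        w <- w / sum(w)
        smoothed[i, ] <- crossprod(dist2[idx, , drop = FALSE], w)
      }
    } else {
      smoothed <- dist2
    }

    new_labels <- max.col(-smoothed, ties.method = "first")
    objective <- c(objective,
                   sum(smoothed[cbind(seq_len(n), new_labels)]))

    converged <- all(new_labels == labels)
    labels <- new_labels
    # drop empty clusters
    ks2 <- sort(unique(labels))
    labels <- match(labels, ks2)
    if (converged) break
  }

  # final statistics recomputed from the converged labels
  K <- length(unique(labels))
  nk <- tabulate(labels, K)
  centroids <- matrix(0, K, p)
  for (k in seq_len(K)) {
    centroids[k, ] <- colMeans(X[labels == k, , drop = FALSE])
  }
  ss <- numeric(p)
  for (k in seq_len(K)) {
    d <- sweep(X[labels == k, , drop = FALSE], 2, centroids[k, ])
    ss <- ss + colSums(d^2)
  }
  sj <- sqrt(ss / max(n - K, 1))
  s0 <- stats::median(sj)
  scale_j <- sj + s0
  if (all(scale_j == 0)) scale_j <- rep(1, p)
  mk <- sqrt(pmax(1 / nk - 1 / n, 0))
  mk[mk == 0] <- 1e-12
  dkj <- sweep(centroids, 2, global_mean) / (mk %o% scale_j)
  tstats <- sign(dkj) * pmax(abs(dkj) - params$s, 0)
  structure(
    list(labels = labels, centroids = centroids,
         tstats = tstats,
         n_iterations = iter, objective = objective, params = params,
         coords = coords, feature_axis = matrix$feature_axis),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d pixels, %d clusters, %d iterations\n",
              length(x$labels), nrow(x$centroids), x$n_iterations))
  invisible(x)
}

#' Select the clusters that cover a reference tumor annotation
#'
#' Returns the pixels of every cluster whose overlap with a reference
#' mask (the stand-in for the pathologist's HE-stain tumor annotation)
#' reaches the threshold. Overlap is the Jaccard index by default;
#' `"precision"` uses the fraction of cluster pixels inside the mask,
#' which is robust when one tumor splits into several clusters.
#'
#' @param segmentation a [spatial_shrunken_centroids()] result.
#' @param reference_mask non-empty data.frame (`x`, `y`) of annotated
#'   tumor pixels; must be a subset of the segmented pixels.
#' @param threshold overlap threshold (default 0.5).
#' @param metric `"jaccard"` or `"precision"`.
#' @return data.frame (`x`, `y`, `cluster`) of selected pixels.
#' @export
select_tumor_clusters <- function(segmentation, reference_mask,
                                  threshold = 0.5,
                                  metric = c("jaccard", "precision")) {
  metric <- match.arg(metric)
  reference_mask <- as.data.frame(reference_mask)
  if (nrow(reference_mask) == 0) stopf("reference mask is empty")
  key <- paste(segmentation$coords$x, segmentation$coords$y)
  mkey <- paste(as.integer(reference_mask$x), as.integer(reference_mask$y))
  if (!all(mkey %in% key)) stopf("reference mask contains non-dataset pixels")
  in_mask <- key %in% mkey
  selected <- logical(length(key))
  for (k in sort(unique(segmentation$labels))) {
    in_k <- segmentation$labels == k
    inter <- sum(in_k & in_mask)
    overlap <- switch(metric,
      jaccard = inter / sum(in_k | in_mask),
      precision = inter / sum(in_k)
    )
    if (overlap >= threshold) selected <- selected | in_k
  }
  data.frame(x = segmentation$coords$x[selected],
             y = segmentation$coords$y[selected],
             cluster = segmentation$labels[selected])
}

#' Group proteomics extraction spots by MSI cluster
#'
#' Builds the two-group contrast design consumed by [volcano_compare()]:
#' each extraction spot is assigned to the intra-tumor cluster containing
#' it. A spot overlapping both clusters is an error; a spot outside both
#' is excluded with a warning; an empty group is an error.
#'
#' @param cluster_a_pixels,cluster_b_pixels data.frames (`x`, `y`) of the
#'   two clusters' pixels.
#' @param spot_assignments data.frame with columns `sample_id`, `x`, `y`
#'   giving each extraction spot's pixel position.
#' @return list with character vectors `group_a` and `group_b` of sample
#'   ids.
#' @export
compare_regions <- function(cluster_a_pixels, cluster_b_pixels,
                            spot_assignments) {
  akey <- paste(cluster_a_pixels$x, cluster_a_pixels$y)
  bkey <- paste(cluster_b_pixels$x, cluster_b_pixels$y)
  if (length(intersect(akey, bkey)) > 0) {
    stopf("cluster pixel sets overlap; regions must be disjoint")
  }
  skey <- paste(spot_assignments$x, spot_assignments$y)
  in_a <- skey %in% akey
  in_b <- skey %in% bkey
  outside <- !in_a & !in_b
  if (any(outside)) {
    warnf("%d extraction spot(s) outside both clusters excluded: %s",
          sum(outside),
          paste(spot_assignments$sample_id[outside], collapse = ", "))
  }
  ga <- spot_assignments$sample_id[in_a]
  gb <- spot_assignments$sample_id[in_b]
  if (length(ga) == 0 || length(gb) == 0) {
    stopf("one comparison group is empty")
  }
  list(group_a = ga, group_b = gb)
}
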