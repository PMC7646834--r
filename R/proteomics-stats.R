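# Table statistics on label-free protein quantification data: flag
# filtering, log transform, valid-value filtering, one-way ANOVA with BH
# FDR, down-shifted normal imputation, Z-scoring, hierarchical clustering,
# PCA with 95% prediction ellipses, and the two-group volcano contrast.
#
# Pipeline order matters and is enforced through the table's scale field
# and explicit missing values: flag filter -> log transform -> valid-value
# filter -> ANOVA on unimputed values; imputation only feeds PCA and
# classification.

#' Remove flagged rows from a protein table
#'
#' Drops every protein carrying any of the contaminant / reverse /
#' only-identified-by-site flags. Removal counts per flag are attached as
#' the `"removed"` attribute.
#'
#' @param table a [protein_quant_table()].
#' @return the filtered table.
#' @export
filter_flags <- function(table) {
  drop <- table$flags$contaminant | table$flags$reverse |
    table$flags$only_by_site
  out <- subset_proteins(table, !drop)
  attr(out, "removed") <- c(
    contaminant = sum(table$flags$contaminant),
    reverse = sum(table$flags$reverse),
    only_by_site = sum(table$flags$only_by_site),
    total = sum(drop)
  )
  out
}

#' Log-transform a raw protein table
#'
#' Present values are replaced by their base-`base` logarithm; missing
#' stays missing. Applying the transform twice is an error (the scale
#' field guards it).
#'
#' @param table a raw-scale [protein_quant_table()].
#' @param base logarithm base (default 2).
#' @return the table on log2 scale.
#' @export
log_transform <- function(table, base = 2) {
  if (table$scale != "raw") {
    stopf("table is already log-transformed (scale = %s)", table$scale)
  }
  bad <- which(table$intensities <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stopf("non-positive intensity for protein %s, sample %s",
          table$protein_ids[bad[1, 1]],
          table$sample_meta$sample_id[bad[1, 2]])
  }
  table$intensities <- log(table$intensities, base = base)
  table$scale <- "log2"
  table
}

#' Keep proteins quantified in a minimum fraction of samples
#'
#' A protein is kept iff its valid (non-missing) count divided by the
#' number of samples is at least `min_fraction` (inclusive, so 7 of 10
#' passes at 0.70).
#'
#' @param table a [protein_quant_table()].
#' @param min_fraction minimum valid fraction in (0, 1] (default 0.70).
#' @return the filtered table.
#' @export
filter_valid <- function(table, min_fraction = 0.70) {
  if (min_fraction <= 0 || min_fraction > 1) {
    stopf("min_fraction must be in (0, 1]")
  }
  valid <- rowSums(!is.na(table$intensities))
  keep <- valid / n_samples(table) >= min_fraction
  subset_proteins(table, keep)
}

#' One-way ANOVA per protein with Benjamini-Hochberg FDR control
#'
#' Classic (equal-variance) one-way ANOVA on the valid values of each
#' protein across classes; BH step-up over all testable proteins.
#' Proteins with fewer than 2 valid values in 2 or more classes are
#' untestable (NA statistics, never significant). Run this on unimputed
#' values.
#'
#' @param table a log2-scale [protein_quant_table()].
#' @param class_labels per-sample class (default: the table's own
#'   `sample_meta$class`); at least 2 classes required.
#' @param fdr FDR threshold (default 0.01).
#' @return object of class `differential_result`: data.frame with group
#'   means, F statistic, p value, BH-adjusted q value and `significant`
#'   flag per protein.
#' @export
anova_bh <- function(table, class_labels = NULL, fdr = 0.01) {
  if (is.null(class_labels)) class_labels <- table$sample_meta$class
  class_labels <- as.character(class_labels)
  classes <- unique(class_labels)
  if (length(classes) < 2) stopf("ANOVA requires at least 2 classes")
  vals <- table$intensities
  n_prot <- nrow(vals)

  res <- data.frame(protein_id = table$protein_ids,
                    stringsAsFactors = FALSE)
  for (cls in classes) {
    res[[paste0("mean_", cls)]] <-
      rowMeans(vals[, class_labels == cls, drop = FALSE], na.rm = TRUE)
  }
  fstat <- rep(NA_real_, n_prot)
  pval <- rep(NA_real_, n_prot)
  for (i in seq_len(n_prot)) {
    y <- vals[i, ]
    ok <- !is.na(y)
    g <- factor(class_labels[ok])
    counts <- tabulate(g)
    if (nlevels(g) < 2 || any(counts < 2)) next
    ft <- stats::oneway.test(y[ok] ~ factor(g), var.equal = TRUE)
    fstat[i] <- unname(ft$statistic)
    pval[i] <- ft$p.value
  }
  qval <- rep(NA_real_, n_prot)
  tested <- !is.na(pval)
  qval[tested] <- stats::p.adjust(pval[tested], method = "BH")
  res$F <- fstat
  res$p <- pval
  res$q <- qval
  res$significant <- !is.na(qval) & qval <= fdr
  structure(list(result = res, fdr = fdr, classes = classes),
            class = "differential_result")
}

#' @export
print.differential_result <- function(x, ...) {
  cat(sprintf(
    "<differential_result> %d proteins, %d tested, %d significant at FDR %.3g\n",
    nrow(x$result), sum(!is.na(x$result$p)), sum(x$result$significant), x$fdr
  ))
  invisible(x)
}

#' Keep the proteins a differential result calls significant
#'
#' @param table a [protein_quant_table()].
#' @param diff a [anova_bh()] result computed on the same table.
#' @return the filtered table.
#' @export
filter_significant <- function(table, diff) {
  keep <- table$protein_ids %in%
    diff$result$protein_id[diff$result$significant]
  subset_proteins(table, keep)
}

#' Impute missing values from a down-shifted normal distribution
#'
#' Per sample column: missing entries are drawn from
#' `Normal(mu - downshift * sigma, (width * sigma)^2)` where `mu` and
#' `sigma` are that column's valid-value mean and SD. This mimics the
#' missing-not-at-random mechanism of label-free data, placing imputed
#' values at the low-abundance tail. Valid values are never altered.
#'
#' @param table a log2-scale [protein_quant_table()].
#' @param width imputation SD as a fraction of the column SD
#'   (default 0.3).
#' @param downshift distribution shift in column SDs (default 1.8).
#' @param seed integer seed; imputation is deterministic given it.
#' @return the completed table (no missing values).
#' @export
impute_normal <- function(table, width = 0.3, downshift = 1.8, seed = 1) {
  if (table$scale != "log2") stopf("impute on the log2 scale")
  vals <- table$intensities
  with_seed(derive_seed(seed, "impute"), {
    for (j in seq_len(ncol(vals))) {
      col <- vals[, j]
      miss <- is.na(col)
      if (!any(miss)) next
      valid <- col[!miss]
      if (length(valid) < 3) {
        stopf("column %s has fewer than 3 valid values",
              table$sample_meta$sample_id[j])
      }
      mu <- mean(valid)
      sigma <- stats::sd(valid)
      vals[miss, j] <- stats::rnorm(sum(miss),
                                    mean = mu - downshift * sigma,
                                    sd = width * sigma)
    }
  })
  table$intensities <- vals
  table
}

#' Z-score rows of a matrix or protein table
#'
#' Per row: subtract the mean, divide by the population standard
#' deviation (N denominator), so each row ends with mean 0 and
#' population SD 1; a row (1, 2, 3) becomes (-1.2247, 0, 1.2247).
#' A constant row is an error naming the protein.
#'
#' @param x numeric matrix or complete [protein_quant_table()].
#' @return same shape as the input.
#' @export
zscore_rows <- function(x) {
  vals <- if (inherits(x, "protein_quant_table")) x$intensities else as.matrix(x)
  if (ncol(vals) < 2) stopf("rows of length < 2 cannot be Z-scored")
  if (any(is.na(vals))) stopf("Z-scoring requires a complete matrix (impute first)")
  sds <- sqrt(rowMeans((vals - rowMeans(vals))^2))
  if (any(sds == 0)) {
    bad <- which(sds == 0)[1]
    stopf("constant row cannot be Z-scored: %s",
          if (!is.null(rownames(vals))) rownames(vals)[bad] else bad)
  }
  z <- (vals - rowMeans(vals)) / sds
  if (inherits(x, "protein_quant_table")) {
    x$intensities <- z
    x
  } else z
}

#' Agglomerative hierarchical clustering of rows or columns
#'
#' Defaults to correlation distance (1 - Pearson) with average linkage,
#' the convention of the heatmap visualizations this feeds; Euclidean
#' distance and other linkages are available. Merge heights are
#' non-decreasing for the supported linkages.
#'
#' @param x numeric matrix or complete [protein_quant_table()].
#' @param axis cluster `"columns"` (samples; default) or `"rows"`
#'   (proteins).
#' @param distance `"correlation"` or `"euclidean"`.
#' @param linkage linkage method passed to [stats::hclust()] (default
#'   `"average"`).
#' @return list with `tree` (an `hclust`), `order` (leaf order) and
#'   `labels`.
#' @export
hcluster <- function(x, axis = c("columns", "rows"),
                     distance = c("correlation", "euclidean"),
                     linkage = "average") {
  axis <- match.arg(axis)
  distance <- match.arg(distance)
  vals <- if (inherits(x, "protein_quant_table")) x$intensities else as.matrix(x)
  if (axis == "columns") vals <- t(vals)
  if (nrow(vals) < 2) stopf("need at least 2 items to cluster")
  if (any(!is.finite(vals))) stopf("non-finite values; impute first")
  d <- switch(distance,
    correlation = stats::as.dist(1 - stats::cor(t(vals))),
    euclidean = stats::dist(vals)
  )
  tree <- stats::hclust(d, method = linkage)
  list(tree = tree, order = tree$order, labels = rownames(vals))
}

#' PCA with per-group 95% prediction ellipses
#'
#' PCA scores of the samples plus, per group, the 2D prediction ellipse
#' on the first two components: the region in which a new observation
#' from the same group falls with the stated probability, based on the
#' F distribution,
#' `(x - m)' S^{-1} (x - m) <= 2 (n-1)(n+1) / (n (n-2)) * F(level; 2, n-2)`.
#' Groups smaller than 3 get no ellipse (warning).
#'
#' @param x samples x features matrix, [feature_matrix()], or complete
#'   [protein_quant_table()] (samples = columns).
#' @param groups per-sample group labels.
#' @param level prediction level (default 0.95).
#' @param n_components PCA components to return (default 4).
#' @return list with `scores`, `explained_variance`, and `ellipses`: per
#'   group a list (center, cov, radius2, n) describing the PC1-2
#'   prediction region.
#' @export
pca_with_ellipses <- function(x, groups, level = 0.95, n_components = 4) {
  vals <- if (inherits(x, "protein_quant_table")) t(x$intensities)
          else as_values(x)
  if (any(is.na(vals))) stopf("PCA requires a complete matrix (impute first)")
  groups <- as.character(groups)
  if (length(groups) != nrow(vals)) stopf("one group label per sample required")
  pc <- pca_scores(vals, n_components = min(n_components, nrow(vals) - 1))
  sc <- pc$scores[, 1:2, drop = FALSE]
  ellipses <- list()
  for (g in unique(groups)) {
    idx <- groups == g
    if (sum(idx) < 3) {
      warnf("group %s has %d sample(s); ellipse omitted", g, sum(idx))
      next
    }
    ellipses[[g]] <- prediction_ellipse(sc[idx, , drop = FALSE], level)
  }
  list(scores = pc$scores, explained_variance = pc$explained_variance,
       ellipses = ellipses, groups = groups)
}

#' 2D prediction ellipse of a point cloud
#'
#' F-distribution-based region in which a new observation from the same
#' population falls with probability `level`:
#' `(x - m)' S^{-1} (x - m) <= 2 (n-1)(n+1) / (n (n-2)) F(level; 2, n-2)`.
#'
#' @param points numeric matrix with 2 columns (n >= 3 rows).
#' @param level prediction level (default 0.95).
#' @return list (center, cov, radius2, n, level) as consumed by
#'   [in_ellipse()].
#' @export
prediction_ellipse <- function(points, level = 0.95) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(pts)
  if (n < 3) stopf("a prediction ellipse needs at least 3 points")
  list(
    center = colMeans(pts),
    cov = stats::cov(pts),
    radius2 = 2 * (n - 1) * (n + 1) / (n * (n - 2)) *
      stats::qf(level, 2, n - 2),
    n = n, level = level
  )
}

#' Test whether 2D points fall inside a prediction ellipse
#'
#' @param points numeric matrix (rows = points, 2 columns) or length-2
#'   vector.
#' @param ellipse one element of `pca_with_ellipses()$ellipses`.
#' @return logical vector.
#' @export
in_ellipse <- function(points, ellipse) {
  pts <- if (is.null(dim(points))) matrix(points, nrow = 1) else as.matrix(points)
  d <- sweep(pts[, 1:2, drop = FALSE], 2, ellipse$center)
  md2 <- rowSums((d %*% solve(ellipse$cov)) * d)
  md2 <= ellipse$radius2
}

#' Two-group volcano comparison
#'
#' Welch (unequal-variance) two-sample t-test per protein on log2 values,
#' significance requiring both `p <= p_max` and an absolute mean log2
#' difference of at least `log2(min_fold)`. The signed difference is
#' B minus A (positive = up in B). Proteins with fewer than 2 valid
#' values on either side are untestable.
#'
#' @param table a log2-scale [protein_quant_table()].
#' @param group_a_samples,group_b_samples non-empty sample id vectors.
#' @param p_max p-value threshold (default 0.01).
#' @param min_fold minimal fold difference (default 2, i.e. 1 log2 unit).
#' @return data.frame per protein: `mean_a`, `mean_b`, `difference`
#'   (B - A), `p`, `significant`, `direction`.
#' @export
volcano_compare <- function(table, group_a_samples, group_b_samples,
                            p_max = 0.01, min_fold = 2) {
  if (table$scale != "log2") stopf("volcano comparison expects log2 values")
  if (length(group_a_samples) == 0 || length(group_b_samples) == 0) {
    stopf("both comparison groups must be non-empty")
  }
  ids <- table$sample_meta$sample_id
  ia <- match(group_a_samples, ids)
  ib <- match(group_b_samples, ids)
  if (anyNA(ia) || anyNA(ib)) stopf("unknown sample id in comparison groups")
  A <- table$intensities[, ia, drop = FALSE]
  B <- table$intensities[, ib, drop = FALSE]
  n <- nrow(A)
  out <- data.frame(protein_id = table$protein_ids,
                    mean_a = rowMeans(A, na.rm = TRUE),
                    mean_b = rowMeans(B, na.rm = TRUE),
                    difference = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  out$difference <- out$mean_b - out$mean_a
  for (i in seq_len(n)) {
    a <- A[i, ][!is.na(A[i, ])]
    b <- B[i, ][!is.na(B[i, ])]
    if (length(a) < 2 || length(b) < 2) next
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      out$p[i] <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
      next
    }
    out$p[i] <- stats::t.test(b, a)$p.value
  }
  out$significant <- !is.na(out$p) & out$p <= p_max &
    abs(out$difference) >= log2(min_fold)
  out$direction <- ifelse(!out$significant, "ns",
                          ifelse(out$difference > 0, "up_in_b", "down_in_b"))
  out
}
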