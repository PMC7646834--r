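# Perseus-style protein table statistics.

# Minimal hand-built raw table: 3 classes x 2 samples each.
mini_table <- function(vals, classes = rep(tumor_classes(), each = 2),
                       flags = NULL) {
  n <- nrow(vals)
  protein_quant_table(
    protein_ids = sprintf("P%03d", seq_len(n)),
    intensities = vals,
    sample_meta = data.frame(
      sample_id = sprintf("s%d", seq_len(ncol(vals))),
      patient_id = sprintf("pat%d", seq_len(ncol(vals))),
      class = classes, spot_id = 1
    ),
    flags = flags
  )
}

test_that("flag filtering removes exactly the flagged rows", {
  vals <- matrix(2^stats::rnorm(100 * 6, 20), 100)
  flags <- data.frame(contaminant = rep(FALSE, 100),
                      reverse = rep(FALSE, 100),
                      only_by_site = rep(FALSE, 100))
  flags$contaminant[1:5] <- TRUE
  flags$reverse[6:8] <- TRUE
  tab <- mini_table(vals, flags = flags)
  out <- filter_flags(tab)
  expect_equal(nrow(out$intensities), 92)
  expect_equal(attr(out, "removed")[["total"]], 8)
  # doubly-flagged row removed once
  flags$reverse[1] <- TRUE
  out2 <- filter_flags(mini_table(vals, flags = flags))
  expect_equal(nrow(out2$intensities), 92)
  # no flags: identity
  clean <- mini_table(vals)
  expect_equal(nrow(filter_flags(clean)$intensities), 100)
})

test_that("log transform is guarded and preserves missingness", {
  vals <- matrix(1024, 2, 6)
  vals[1, 2] <- NA
  tab <- mini_table(vals)
  out <- log_transform(tab)
  expect_equal(out$intensities[2, 1], 10)
  expect_true(is.na(out$intensities[1, 2]))
  expect_equal(out$scale, "log2")
  expect_error(log_transform(out), "already log-transformed")
})

test_that("valid-value filter uses an inclusive threshold", {
  vals <- matrix(2, 3, 10)
  vals[1, 1:3] <- NA   # 7/10 valid: kept at 0.70
  vals[2, 1:4] <- NA   # 6/10 valid: dropped
  tab <- mini_table(vals, classes = rep(tumor_classes(), length.out = 10))
  out <- filter_valid(tab, 0.70)
  expect_equal(out$protein_ids, c("P001", "P003"))
  # min_fraction = 1: only complete rows survive
  expect_equal(filter_valid(tab, 1)$protein_ids, "P003")
})

test_that("ANOVA detects a planted shift and marks untestable proteins", {
  set.seed(4)
  n_per <- 6
  vals <- matrix(stats::rnorm(3 * 3 * n_per, 20, 1), nrow = 3)
  classes <- rep(tumor_classes(), each = n_per)
  vals[1, classes == "ccRCC"] <- vals[1, classes == "ccRCC"] + 5  # 5 sigma
  vals[3, classes == "RO"] <- NA
  vals[3, which(classes == "ChRCC")[-1]] <- NA  # 1 valid ChRCC value
  tab <- mini_table(2^vals, classes = classes)
  res <- anova_bh(log_transform(tab), fdr = 0.01)
  expect_true(res$result$significant[1])
  expect_true(is.na(res$result$p[3]))          # untestable, not significant
  expect_false(res$result$significant[3])
  # q >= p and significance implies q <= fdr
  ok <- !is.na(res$result$p)
  expect_true(all(res$result$q[ok] >= res$result$p[ok]))
  expect_true(all(res$result$q[res$result$significant] <= 0.01))
  expect_error(anova_bh(log_transform(tab), class_labels = rep("RO", 18)),
               "2 classes")
})

test_that("imputation draws from the down-shifted column model", {
  # no-missing column unchanged; same seed reproduces
  vals <- matrix(stats::rnorm(60, 20, 2), 10)
  tab <- mini_table(2^vals)
  tab <- log_transform(tab)
  same <- impute_normal(tab, seed = 3)
  expect_equal(same$intensities, tab$intensities)
  tab$intensities[c(2, 5), 1] <- NA
  a <- impute_normal(tab, seed = 3)
  b <- impute_normal(tab, seed = 3)
  expect_identical(a$intensities, b$intensities)
  # valid entries never altered
  mask <- !is.na(tab$intensities)
  expect_identical(a$intensities[mask], tab$intensities[mask])
  # < 3 valid values in a column
  tab$intensities[3:10, 1] <- NA
  expect_error(impute_normal(tab, seed = 1), "fewer than 3 valid")
})

test_that("Z-scoring matches the closed form and guards constants", {
  z <- zscore_rows(matrix(c(1, 2, 3), 1))
  expect_equal(as.vector(z), c(-1, 0, 1) * 1.224745, tolerance = 1e-6)
  expect_equal(zscore_rows(z), z, tolerance = 1e-12)
  expect_error(zscore_rows(matrix(5, 2, 4)), "constant row")
  expect_error(zscore_rows(matrix(1, 1, 1)), "length < 2")
})

test_that("hierarchical clustering merges identical columns first", {
  set.seed(6)
  m <- matrix(stats::rnorm(40), 10)
  m <- cbind(m, m[, 2])  # column 5 duplicates column 2
  hc <- hcluster(m, axis = "columns", distance = "euclidean",
                 linkage = "single")
  expect_equal(hc$tree$height[1], 0)
  expect_setequal(abs(hc$tree$merge[1, ]), c(2, 5))
  expect_true(all(diff(hc$tree$height) >= -1e-12))
})

test_that("sample clustering recovers the synthetic classes", {
  tab <- generate_protein_table(small_design(seed = 8))
  tab <- log_transform(filter_flags(tab))
  hc <- hcluster(zscore_rows(tab), axis = "columns")
  k3 <- stats::cutree(hc$tree, 3)
  expect_gte(adjusted_rand_index(k3, tab$sample_meta$class), 0.9)
})

test_that("single-linkage tree on 4 points equals the exhaustive oracle", {
  x <- matrix(c(0, 1.1, 3.0, 7.0), ncol = 1)
  # brute-force single linkage by enumeration over cluster pairs
  clusters <- as.list(1:4)
  heights <- numeric(0)
  merges <- list()
  d <- as.matrix(stats::dist(x))
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- min(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, j, i)
      }
    }
    heights <- c(heights, best[1])
    merges <- c(merges, list(sort(c(clusters[[best[2]]], clusters[[best[3]]]))))
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  hc <- hcluster(x, axis = "rows", distance = "euclidean", linkage = "single")
  expect_equal(hc$tree$height, heights)
  # final merge memberships agree at every level
  for (k in 1:3) {
    cut_mine <- stats::cutree(hc$tree, k = 4 - k)
    grp <- cut_mine[merges[[k]]]
    expect_equal(length(unique(grp)), 1)
  }
})

test_that("PCA prediction ellipses are produced per group with guards", {
  set.seed(12)
  x <- rbind(matrix(stats::rnorm(60), 20), matrix(stats::rnorm(60, 4), 20))
  groups <- rep(c("A", "B"), each = 20)
  pe <- pca_with_ellipses(x, groups)
  expect_named(pe$ellipses, c("A", "B"))
  expect_true(all(vapply(pe$ellipses, function(e) e$radius2 > 0, logical(1))))
  # group of 2: warning, ellipse omitted
  expect_warning(
    pe2 <- pca_with_ellipses(x[c(1:20, 21:22), ], c(groups[1:20], "B", "B")),
    "omitted")
  expect_null(pe2$ellipses$B)
})

test_that("volcano comparison applies both thresholds with signed direction", {
  set.seed(3)
  n <- 8
  a <- matrix(stats::rnorm(3 * n, 20, 0.2), nrow = 3)
  b <- a
  b[1, ] <- b[1, ] + 1.0     # up in B, tiny p
  b[2, ] <- b[2, ] + 3.0     # large shift but huge noise
  b[2, ] <- b[2, ] + stats::rnorm(n, 0, 6)
  tab <- mini_table(2^cbind(a, b), classes = rep(c("A", "B"), each = n))
  tab <- log_transform(tab)
  res <- volcano_compare(tab, sprintf("s%d", 1:n), sprintf("s%d", n + 1:n),
                         p_max = 0.01, min_fold = 2)
  expect_true(res$significant[1])
  expect_equal(res$direction[1], "up_in_b")
  expect_false(res$significant[2])   # p above threshold despite the shift
  expect_false(res$significant[3])   # no difference
  expect_error(volcano_compare(tab, character(0), "s9"), "non-empty")
})

test_that("null volcano without a fold gate rejects at about the p threshold", {
  set.seed(21)
  n_prot <- 400; n <- 10
  vals <- matrix(stats::rnorm(n_prot * 2 * n, 20, 1), n_prot)
  tab <- mini_table(2^vals, classes = rep(c("A", "B"), each = n))
  res <- volcano_compare(log_transform(tab),
                         sprintf("s%d", 1:n), sprintf("s%d", n + 1:n),
                         p_max = 0.05, min_fold = 1)
  rate <- mean(res$significant)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_prot))
})
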