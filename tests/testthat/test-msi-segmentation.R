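# Spatially-aware shrunken-centroid segmentation.

seg_features <- function(ds) {
  peaks <- align_peaks(pick_peaks(ds, stride = 1, snr_min = 3), 0.25)
  resample_height(ds, peaks)
}

test_that("r=0, s=0 reduces to a plain k-means partition", {
  blobs <- make_blobs(n_per_class = 15, p = 4, sep = 10, seed = 3)
  fm <- feature_matrix(abs(blobs$x), seq_len(ncol(blobs$x)),
                       sprintf("r%02d", seq_len(nrow(blobs$x))),
                       data.frame(x = rep(1:9, 5), y = rep(1:5, each = 9)))
  seg <- spatial_shrunken_centroids(
    fm, params = segmentation_params(k_init = 3, r = 0, s = 0, seed = 5)
  )
  set.seed(5)
  km <- stats::kmeans(fm$values, 3, nstart = 3)
  expect_equal(adjusted_rand_index(seg$labels, km$cluster), 1)
  expect_equal(adjusted_rand_index(seg$labels, blobs$labels), 1)
})

test_that("saturating shrinkage collapses everything into one cluster", {
  ds <- generate_msi_phantom(clean_phantom_spec(grid = 6))
  fm <- seg_features(ds)
  seg <- spatial_shrunken_centroids(
    fm, params = segmentation_params(k_init = 3, r = 0, s = 1e6, seed = 1)
  )
  expect_equal(nrow(seg$centroids), 1)
  expect_true(all(seg$labels == 1))
})

test_that("two-region noise-free phantom is segmented perfectly", {
  regions <- list(rect_region(1, 5, 1, 10, "RO"),
                  rect_region(6, 10, 1, 10, "ChRCC"))
  ds <- generate_msi_phantom(clean_phantom_spec(regions = regions, grid = 10))
  fm <- seg_features(ds)
  seg <- spatial_shrunken_centroids(
    fm, params = segmentation_params(k_init = 4, r = 1, s = 0, seed = 2)
  )
  expect_equal(adjusted_rand_index(seg$labels, ground_truth(ds)$label), 1)
})

test_that("within-cluster smoothed distance is non-increasing over iterations", {
  ds <- generate_msi_phantom(msi_phantom_spec(grid_width = 10, grid_height = 10,
                                              seed = 8))
  ds <- subtract_baseline_msi(ds, 50)
  fm <- seg_features(ds)
  seg <- spatial_shrunken_centroids(
    fm, params = segmentation_params(k_init = 4, r = 1, s = 0, seed = 3)
  )
  expect_true(all(diff(seg$objective) <= 1e-8 * max(seg$objective)))
})

test_that("cluster count is non-increasing in the shrinkage threshold", {
  ds <- generate_msi_phantom(msi_phantom_spec(grid_width = 10, grid_height = 10,
                                              seed = 4))
  fm <- seg_features(subtract_baseline_msi(ds, 50))
  sizes <- vapply(c(0, 3, 6, 9), function(s) {
    nrow(spatial_shrunken_centroids(
      fm, params = segmentation_params(k_init = 6, r = 1, s = s, seed = 7)
    )$centroids)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("segmentation is invariant to feature-wise constant offsets", {
  ds <- generate_msi_phantom(clean_phantom_spec(grid = 8))
  fm <- seg_features(ds)
  seg1 <- spatial_shrunken_centroids(
    fm, params = segmentation_params(k_init = 3, r = 1, s = 0, seed = 9)
  )
  fm2 <- fm
  fm2$values <- sweep(fm$values, 2, seq_len(ncol(fm$values)) * 10, `+`)
  seg2 <- spatial_shrunken_centroids(
    fm2, params = segmentation_params(k_init = 3, r = 1, s = 0, seed = 9)
  )
  expect_equal(adjusted_rand_index(seg1$labels, seg2$labels), 1)
})

test_that("segmentation input guards fire", {
  fm <- feature_matrix(matrix(1:4, 2), c(1, 2), c("a", "b"),
                       data.frame(x = 1:2, y = c(1, 1)))
  expect_error(spatial_shrunken_centroids(
    fm, params = segmentation_params(k_init = 5)), "exceeds")
  fm$values[1, 1] <- NA
  expect_error(spatial_shrunken_centroids(
    fm, params = segmentation_params(k_init = 1)), "non-finite")
})

test_that("tumor-cluster selection recovers the annotated region", {
  ds <- generate_msi_phantom(clean_phantom_spec(grid = 10))
  truth <- ground_truth(ds)
  fm <- seg_features(ds)
  seg <- spatial_shrunken_centroids(
    fm, params = segmentation_params(k_init = 4, r = 1, s = 0, seed = 2)
  )
  mask <- truth[truth$label == "ccRCC", c("x", "y")]
  sel <- select_tumor_clusters(seg, mask, metric = "precision")
  expect_setequal(paste(sel$x, sel$y), paste(mask$x, mask$y))
  # a segmentation identical to the mask returns exactly the mask
  expect_error(select_tumor_clusters(seg, mask[0, ]), "empty")
})

test_that("region comparison groups spots by cluster with guards", {
  a <- data.frame(x = 1:4, y = 1)    # cluster 2-analog, 4 spots
  b <- data.frame(x = 1:2, y = 2)    # cluster 1-analog, 2 spots
  spots <- data.frame(sample_id = letters[1:6],
                      x = c(1, 2, 3, 4, 1, 2), y = c(1, 1, 1, 1, 2, 2))
  groups <- compare_regions(a, b, spots)
  expect_equal(groups$group_a, c("a", "b", "c", "d"))
  expect_equal(groups$group_b, c("e", "f"))
  # spot outside both clusters: excluded with a warning
  spots2 <- rbind(spots, data.frame(sample_id = "g", x = 9, y = 9))
  expect_warning(compare_regions(a, b, spots2), "outside")
  # an empty group is an error
  expect_error(
    suppressWarnings(compare_regions(a, data.frame(x = 9, y = 9), spots)),
    "empty"
  )
  # overlapping cluster pixel sets are rejected
  expect_error(compare_regions(a, a, spots), "disjoint")
})
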