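# Synthetic-data generators: deterministic construction, ground truth,
# and the generative model's closed-form expectations.

test_that("noise-free phantom reproduces its specified peak heights exactly", {
  spec <- clean_phantom_spec("ccRCC", grid = 8)
  ds <- generate_msi_phantom(spec)
  truth <- ground_truth(ds)
  axis <- ds$mz
  i723 <- which(axis == 723.5)
  expect_length(i723, 1)
  tumor <- which(truth$label == "ccRCC")
  # TIC factor is 1 (cv = 0), peak cv = 0: apex equals the specified mean
  expect_equal(unname(ds$intensities[tumor, i723]),
               rep(120, length(tumor)), tolerance = 1e-12)
  background <- which(truth$label == "background")
  expect_true(all(ds$intensities[background, ] == 0))
})

test_that("pixel counts per ground-truth label equal the region mask areas", {
  regions <- list(rect_region(1, 3, 1, 6, "RO"),
                  rect_region(6, 9, 3, 7, "ChRCC"))
  spec <- clean_phantom_spec(regions = regions, grid = 10)
  truth <- ground_truth(generate_msi_phantom(spec))
  expect_equal(sum(truth$label == "RO"), 3 * 6)
  expect_equal(sum(truth$label == "ChRCC"), 4 * 5)
  expect_equal(sum(truth$label == "background"), 100 - 18 - 20)
})

test_that("phantom generation is deterministic and streams split per pixel", {
  regions <- list(rect_region(1, 6, 1, 2, "ccRCC"),
                  rect_region(1, 6, 3, 3, "stroma"))
  spec <- msi_phantom_spec(grid_width = 6, grid_height = 6,
                           regions = regions, seed = 42)
  a <- generate_msi_phantom(spec)
  b <- generate_msi_phantom(spec)
  expect_identical(a$intensities, b$intensities)
  # restricting the grid (same regions) leaves shared pixels unchanged
  spec_small <- msi_phantom_spec(grid_width = 6, grid_height = 3,
                                 regions = regions, seed = 42)
  small <- generate_msi_phantom(spec_small)
  expect_equal(small$intensities, a$intensities[1:18, ])
})

test_that("overlapping regions with conflicting classes are rejected", {
  regions <- list(rect_region(1, 4, 1, 4, "RO"),
                  rect_region(3, 6, 3, 6, "ChRCC"))
  expect_error(generate_msi_phantom(clean_phantom_spec(regions = regions)),
               "conflicting classes")
  # same class overlapping is fine
  regions2 <- list(rect_region(1, 4, 1, 4, "RO"),
                   rect_region(3, 6, 3, 6, "RO"))
  expect_silent(generate_msi_phantom(clean_phantom_spec(regions = regions2)))
})

test_that("phantom spec invariants are enforced", {
  expect_error(msi_phantom_spec(mz_range = c(3000, 600)), "min < max")
  expect_error(msi_phantom_spec(noise_sd = -1), ">= 0")
  bad_sigs <- default_signature_peaks()
  bad_sigs$ccRCC$mz[1] <- 99
  expect_error(msi_phantom_spec(class_signature_peaks = bad_sigs),
               "within mz_range")
})

test_that("ground truth is only available for generator output", {
  ds <- generate_msi_phantom(clean_phantom_spec(grid = 4))
  expect_s3_class(ds, "msi_dataset")
  expect_named(ground_truth(ds), c("x", "y", "label"))
  external <- tiny_msi(matrix(1, 2, 5))
  expect_error(ground_truth(external), "no ground truth")
})

test_that("protein table limit case has no missing values and exact flag counts", {
  design <- small_design(n_contaminant_rows = 5, n_reverse_rows = 2)
  tab <- generate_protein_table(design)
  expect_false(anyNA(tab$intensities))
  expect_equal(sum(tab$flags$contaminant), 5)
  expect_equal(sum(tab$flags$reverse), 2)
  # determinism
  tab2 <- generate_protein_table(design)
  expect_identical(tab$intensities, tab2$intensities)
  # spots per patient within the declared range
  spots <- table(tab$sample_meta$patient_id)
  expect_true(all(spots >= 2 & spots <= 3))
})

test_that("class effect matches the generative mean within 3 SE", {
  design <- small_design(
    seed = 7, class_effect_log2fc = 4,
    patients_per_class = c(ccRCC = 4, RO = 4, ChRCC = 4),
    spots_per_patient_range = c(3, 3),
    spot_noise_sd = 0.05, patient_noise_sd = 0.05
  )
  tab <- generate_protein_table(design)
  truth <- ground_truth(tab)
  log2x <- log2(tab$intensities)
  cls <- tab$sample_meta$class
  prot <- which(truth$protein_truth$class_specific == "ccRCC")[1]
  diff <- mean(log2x[prot, cls == "ccRCC"]) - mean(log2x[prot, cls == "RO"])
  # SE of the mean difference under the generative model (4+4 patients,
  # 3 spots each): sqrt(patient_sd^2 * (1/4 + 1/4) + spot_sd^2 * 2/12)
  se <- sqrt(0.05^2 * (1 / 4 + 1 / 4) + 0.05^2 * (2 / 12))
  expect_lt(abs(diff - 4), 3 * se)
})

test_that("missingness is MNAR: rate decreases with abundance", {
  design <- proteome_design(seed = 3)  # study-default design
  tab <- generate_protein_table(design)
  clean <- filter_flags(tab)
  means <- rowMeans(log2(clean$intensities), na.rm = TRUE)
  miss <- rowMeans(is.na(clean$intensities))
  bins <- cut(means, breaks = stats::quantile(means, 0:4 / 4),
              include.lowest = TRUE)
  rates <- tapply(miss, bins, mean)
  expect_true(all(diff(rates) < 0))
})

test_that("outlier patient mixes the two designed class profiles", {
  design <- small_design(
    seed = 5, class_effect_log2fc = 4,
    spot_noise_sd = 0.05, patient_noise_sd = 0.05,
    outlier_patient = list(class = "ChRCC",
                           weights = c(ChRCC = 0.5, ccRCC = 0.5))
  )
  tab <- generate_protein_table(design)
  truth <- ground_truth(tab)
  out_pid <- unique(truth$sample_truth$patient_id[truth$sample_truth$is_outlier])
  expect_length(out_pid, 1)
  log2x <- log2(tab$intensities)
  meta <- tab$sample_meta
  p_cc <- which(truth$protein_truth$class_specific == "ccRCC")[1]
  out_cols <- meta$patient_id == out_pid
  ro_cols <- meta$class == "RO"
  # a ccRCC-specific protein sits at half its full effect in the outlier
  expect_lt(abs(mean(log2x[p_cc, out_cols]) -
                  (mean(log2x[p_cc, ro_cols]) + 2)), 0.6)
})

test_that("design invariants are enforced", {
  expect_error(small_design(n_proteins_total = 10,
                            n_class_specific_per_class = 5),
               "must not exceed")
  expect_error(small_design(patients_per_class = c(ccRCC = 0, RO = 3, ChRCC = 3)),
               "at least one patient")
  expect_error(small_design(spots_per_patient_range = c(0, 4)), "within")
  expect_error(small_design(outlier_patient = list(
    class = "ChRCC", weights = c(ChRCC = 0.7, ccRCC = 0.7)
  )), "sum to 1")
})

test_that("protein table TSV round trip preserves values, flags and metadata", {
  design <- small_design(seed = 2, n_contaminant_rows = 2,
                         missingness_model = c(intercept = 16, slope = -0.7))
  tab <- generate_protein_table(design)
  path <- file.path(tempdir(), "pg.tsv")
  write_protein_table(tab, path)
  back <- read_protein_table(path)
  expect_equal(back$intensities, tab$intensities, tolerance = 1e-10)
  expect_equal(back$flags, tab$flags)
  expect_equal(back$sample_meta$class, tab$sample_meta$class)
})
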