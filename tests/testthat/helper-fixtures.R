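# Shared fixtures: all synthetic, built in code at test time.

# Noise-free phantom spec: deterministic spectra (no noise, no baseline,
# no TIC variation, zero peak CV), one tumor blob + stroma annulus.
clean_phantom_spec <- function(tumor_class = "ccRCC", grid = 10, seed = 1,
                               regions = NULL) {
  sigs <- default_signature_peaks()
  shared <- default_shared_peaks()
  for (i in seq_along(sigs)) sigs[[i]]$cv <- 0
  shared$cv <- 0
  msi_phantom_spec(
    grid_width = grid, grid_height = grid, regions = regions,
    tumor_class = tumor_class,
    class_signature_peaks = sigs, shared_peaks = shared,
    peak_width_fwhm = 0.5, baseline_amplitude = 0, baseline_decay = 0,
    noise_sd = 0, tic_variation_cv = 0,
    mz_range = c(600, 3000), mz_step = 0.25, seed = seed
  )
}

# Small proteomics design for fast tests.
small_design <- function(seed = 1, ...) {
  args <- list(
    n_proteins_total = 60, n_class_specific_per_class = 5,
    patients_per_class = c(ccRCC = 3, RO = 3, ChRCC = 3),
    spots_per_patient_range = c(2, 3),
    class_effect_log2fc = 3,
    missingness_model = c(intercept = -1e9, slope = 0),
    n_contaminant_rows = 0, n_reverse_rows = 0, n_only_site_rows = 0,
    outlier_patient = NULL, seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(proteome_design, args)
}

# Well-separated Gaussian blobs: one matrix row per sample.
make_blobs <- function(n_per_class = 10, p = 6, sep = 8, noise = 1,
                       seed = 1) {
  classes <- tumor_classes()
  set.seed(seed)
  centers <- matrix(0, 3, p)
  centers[1, 1] <- sep
  centers[2, 2] <- sep
  centers[3, 3] <- sep
  x <- do.call(rbind, lapply(1:3, function(k) {
    matrix(stats::rnorm(n_per_class * p, sd = noise), n_per_class, p) +
      matrix(centers[k, ], n_per_class, p, byrow = TRUE)
  }))
  rownames(x) <- sprintf("s%02d", seq_len(nrow(x)))
  list(x = x, labels = rep(classes, each = n_per_class))
}

# Adjusted Rand index between two partitions (contingency-table formula).
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(v) sum(choose(v, 2))
  sij <- sum_comb(as.vector(tab))
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# Small labeled pixel matrix with two discriminating features per class
# on a known m/z axis, several patients per class.
toy_cohort <- function(n_patients_per_class = 3, pixels_per_patient = 12,
                       noise = 0.3, p_noise = 3, seed = 1) {
  set.seed(seed)
  classes <- tumor_classes()
  axis <- c(704.5, 723.5, 806.5, 1039.5, 1169.5, 1640.0,
            seq(2000, by = 25, length.out = p_noise))
  sig <- list(
    ccRCC = c(723.5, 704.5), RO = c(806.5, 1640.0), ChRCC = c(1169.5, 1039.5)
  )
  rows <- list(); groups <- list(); ids <- character(0)
  pid <- 0
  for (cls in classes) {
    for (k in seq_len(n_patients_per_class)) {
      pid <- pid + 1
      m <- matrix(abs(stats::rnorm(pixels_per_patient * length(axis),
                                   0, noise)),
                  pixels_per_patient)
      m[, match(sig[[cls]], axis)] <-
        m[, match(sig[[cls]], axis)] + 10
      rows[[pid]] <- m
      groups[[pid]] <- data.frame(
        x = seq_len(pixels_per_patient), y = pid,
        patient_id = sprintf("P%02d", pid), condition = cls
      )
      ids <- c(ids, sprintf("P%02d_px%02d", pid, seq_len(pixels_per_patient)))
    }
  }
  feature_matrix(do.call(rbind, rows), axis, ids, do.call(rbind, groups))
}

# Tiny continuous msi_dataset built directly from a matrix.
tiny_msi <- function(intensities, mz = NULL, patient_id = "T") {
  n <- nrow(intensities)
  if (is.null(mz)) mz <- seq(100, 100 + ncol(intensities) - 1)
  msi_dataset(
    coords = data.frame(x = seq_len(n), y = rep(1L, n)),
    mz = mz, intensities = intensities, mode = "continuous",
    patient_id = patient_id
  )
}
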