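# Synthetic MALDI-MSI phantoms with known ground truth.
#
# The generative model per pixel: Gaussian peaks (stated FWHM) at the
# region-class signature m/z plus shared tissue peaks, the whole peak
# profile multiplied by a per-pixel TIC factor, plus an exponentially
# decaying baseline b(m) = A * exp(-lambda * (m - mz_min)), plus i.i.d.
# Gaussian noise; the summed spectrum is clipped at zero. Random streams
# are split per pixel (each pixel draws from its own derived seed) so
# subsetting a region never changes the remaining pixels.

#' Region helpers for phantom specifications
#'
#' `circle_region()` marks all grid pixels within Euclidean distance `r`
#' of (`cx`, `cy`); `annulus_region()` marks pixels with distance in
#' (`r_inner`, `r_outer`]; `rect_region()` marks an axis-aligned rectangle.
#'
#' @param cx,cy circle center (pixels; need not be integer).
#' @param r,r_inner,r_outer radii in pixels.
#' @param x0,x1,y0,y1 inclusive rectangle bounds.
#' @param class region class label (one of [tumor_classes()], `"stroma"`,
#'   `"background"`).
#' @return a list with elements `predicate` (function of x, y matrices)
#'   and `class`, consumed by [msi_phantom_spec()].
#' @export
circle_region <- function(cx, cy, r, class) {
  list(predicate = function(x, y) (x - cx)^2 + (y - cy)^2 <= r^2, class = class)
}

#' @rdname circle_region
#' @export
annulus_region <- function(cx, cy, r_inner, r_outer, class) {
  list(predicate = function(x, y) {
    d2 <- (x - cx)^2 + (y - cy)^2
    d2 > r_inner^2 & d2 <= r_outer^2
  }, class = class)
}

#' @rdname circle_region
#' @export
rect_region <- function(x0, x1, y0, y1, class) {
  list(predicate = function(x, y) x >= x0 & x <= x1 & y >= y0 & y <= y1,
       class = class)
}

#' Default class signature peaks for phantoms
#'
#' The class-discriminating m/z features: 723.5 and 704.5 for ccRCC,
#' 806.5 and 1640.0 for RO, 1169.5 and 1039.5 for ChRCC, plus a stroma
#' signature so segmentation has a non-tumor tissue class to find.
#' Intensities are arbitrary instrument-like units.
#'
#' @return named list of data.frames with columns `mz`, `mean_intensity`,
#'   `cv`.
#' @export
default_signature_peaks <- function() {
  list(
    ccRCC = data.frame(mz = c(723.5, 704.5), mean_intensity = c(120, 100),
                       cv = 0.25),
    RO = data.frame(mz = c(806.5, 1640.0), mean_intensity = c(120, 100),
                    cv = 0.25),
    ChRCC = data.frame(mz = c(1169.5, 1039.5), mean_intensity = c(120, 100),
                       cv = 0.25),
    stroma = data.frame(mz = c(852.0, 976.5), mean_intensity = c(90, 70),
                        cv = 0.25)
  )
}

#' Default shared (class-independent) tissue peaks
#'
#' A small set of peaks present in every tissue pixel regardless of class
#' (e.g. tryptic autolysis and ubiquitous matrix/tissue signals), so that
#' classes are separated by relative rather than total signal.
#'
#' @return data.frame with columns `mz`, `mean_intensity`, `cv`.
#' @export
default_shared_peaks <- function() {
  data.frame(
    mz = c(842.51, 1105.6, 1296.7, 2211.1),
    mean_intensity = c(80, 60, 50, 30),
    cv = 0.2
  )
}

#' Specification of a synthetic MSI phantom
#'
#' Defines the grid, spatial regions, spectral signatures and noise model
#' of one synthetic tissue section. Defaults emulate a 16 x 16 pixel
#' section with a central tumor blob surrounded by a stroma annulus on a
#' background; acquisition range m/z 600-3000 sampled at 0.25 Da, matching
#' a reflector-mode peptide-range export.
#'
#' @param grid_width,grid_height grid size in pixels.
#' @param regions list of region descriptors ([circle_region()] etc.);
#'   later regions must not conflict with earlier ones (overlap with a
#'   different class is an error). Pixels in no region are `"background"`.
#'   `NULL` gives the default blob-plus-annulus layout with the tumor blob
#'   labeled `tumor_class`.
#' @param tumor_class class of the default tumor blob.
#' @param class_signature_peaks named list (class -> data.frame `mz`,
#'   `mean_intensity`, `cv`) of class-specific peaks.
#' @param shared_peaks data.frame of peaks added to every non-background
#'   pixel.
#' @param peak_width_fwhm Gaussian peak full width at half maximum (Da).
#' @param baseline_amplitude,baseline_decay baseline
#'   `A * exp(-lambda (m - mz_min))`: amplitude (a.u.) and decay (1/Da).
#' @param noise_sd standard deviation of additive Gaussian noise (a.u.).
#' @param tic_variation_cv coefficient of variation of the per-pixel TIC
#'   factor (log-normal, mean 1).
#' @param mz_range acquisition range (Da), min < max.
#' @param mz_step axis step (Da).
#' @param seed integer seed; generation is deterministic given the spec.
#' @return object of class `msi_phantom_spec`.
#' @export
msi_phantom_spec <- function(grid_width = 16, grid_height = 16,
                             regions = NULL,
                             tumor_class = "ccRCC",
                             class_signature_peaks = default_signature_peaks(),
                             shared_peaks = default_shared_peaks(),
                             peak_width_fwhm = 0.5,
                             baseline_amplitude = 2,
                             baseline_decay = 0.002,
                             noise_sd = 0.5,
                             tic_variation_cv = 0.15,
                             mz_range = c(600, 3000),
                             mz_step = 0.25,
                             seed = 1) {
  if (!is_count(grid_width, 1) || !is_count(grid_height, 1)) {
    stopf("grid dimensions must be positive integers")
  }
  if (length(mz_range) != 2 || mz_range[1] >= mz_range[2]) {
    stopf("mz_range must satisfy min < max")
  }
  if (noise_sd < 0 || tic_variation_cv < 0) {
    stopf("noise_sd and tic_variation_cv must be >= 0")
  }
  if (peak_width_fwhm <= 0 || mz_step <= 0) {
    stopf("peak_width_fwhm and mz_step must be > 0")
  }
  all_peaks <- rbind(
    do.call(rbind, unname(class_signature_peaks)),
    shared_peaks
  )
  if (!is.null(all_peaks) && nrow(all_peaks) > 0) {
    if (any(all_peaks$cv < 0)) stopf("peak cv must be >= 0")
    if (any(all_peaks$mz < mz_range[1] | all_peaks$mz > mz_range[2])) {
      stopf("all signature/shared m/z must lie within mz_range")
    }
  }
  if (is.null(regions)) {
    cx <- (grid_width + 1) / 2
    cy <- (grid_height + 1) / 2
    r_tumor <- min(grid_width, grid_height) * 0.28
    regions <- list(
      circle_region(cx, cy, r_tumor, tumor_class),
      annulus_region(cx, cy, r_tumor, r_tumor + 2, "stroma")
    )
  }
  structure(
    list(
      grid_width = grid_width, grid_height = grid_height, regions = regions,
      class_signature_peaks = class_signature_peaks,
      shared_peaks = shared_peaks, peak_width_fwhm = peak_width_fwhm,
      baseline_amplitude = baseline_amplitude,
      baseline_decay = baseline_decay, noise_sd = noise_sd,
      tic_variation_cv = tic_variation_cv, mz_range = mz_range,
      mz_step = mz_step, seed = as.integer(seed)
    ),
    class = "msi_phantom_spec"
  )
}

# Resolve per-pixel ground-truth labels from region masks; overlap with
# conflicting classes is an error.
resolve_region_labels <- function(spec) {
  grid <- expand.grid(x = seq_len(spec$grid_width),
                      y = seq_len(spec$grid_height))
  labels <- rep("background", nrow(grid))
  for (region in spec$regions) {
    inside <- region$predicate(grid$x, grid$y)
    if (!any(inside)) next
    conflict <- inside & labels != "background" & labels != region$class
    if (any(conflict)) {
      i <- which(conflict)[1]
      stopf("regions overlap with conflicting classes at pixel (%d, %d): %s vs %s",
            grid$x[i], grid$y[i], labels[i], region$class)
    }
    labels[inside] <- region$class
  }
  cbind(grid, label = labels, stringsAsFactors = FALSE)
}

#' Generate a synthetic MSI dataset from a phantom specification
#'
#' Renders one spectrum per grid pixel on the common m/z axis under the
#' generative model described in the package documentation. The returned
#' dataset carries per-pixel ground-truth region labels recoverable via
#' [ground_truth()].
#'
#' @param spec an [msi_phantom_spec()].
#' @param patient_id optional patient identifier stored in the metadata.
#' @return an [msi_dataset()] (continuous mode) with ground truth attached.
#' @export
generate_msi_phantom <- function(spec, patient_id = NULL) {
  if (!inherits(spec, "msi_phantom_spec")) stopf("spec must be an msi_phantom_spec")
  grid <- resolve_region_labels(spec)
  axis <- seq(spec$mz_range[1], spec$mz_range[2], by = spec$mz_step)
  n_mz <- length(axis)
  n_px <- nrow(grid)
  sigma <- spec$peak_width_fwhm / (2 * sqrt(2 * log(2)))
  baseline <- spec$baseline_amplitude *
    exp(-spec$baseline_decay * (axis - spec$mz_range[1]))
  sdlog <- sqrt(log(1 + spec$tic_variation_cv^2))

  # Precompute the Gaussian template support once (in axis index offsets).
  half_pts <- max(1L, ceiling(5 * sigma / spec$mz_step))

  add_peak <- function(intensity_vec, mz0, height) {
    center <- round((mz0 - spec$mz_range[1]) / spec$mz_step) + 1
    lo <- max(1L, center - half_pts)
    hi <- min(n_mz, center + half_pts)
    if (lo > hi) return(intensity_vec)
    idx <- lo:hi
    intensity_vec[idx] <- intensity_vec[idx] +
      height * exp(-((axis[idx] - mz0)^2) / (2 * sigma^2))
    intensity_vec
  }

  intens <- matrix(0, nrow = n_px, ncol = n_mz)
  for (i in seq_len(n_px)) {
    label <- grid$label[i]
    peaks <- spec$class_signature_peaks[[label]]
    if (label != "background") peaks <- rbind(peaks, spec$shared_peaks)
    pixel_seed <- derive_seed(spec$seed, "pixel",
                              (grid$y[i] - 1) * spec$grid_width + grid$x[i])
    spectrum <- with_seed(pixel_seed, {
      tic_factor <- if (spec$tic_variation_cv > 0) {
        exp(stats::rnorm(1, mean = -sdlog^2 / 2, sd = sdlog))
      } else 1
      s <- numeric(n_mz)
      if (!is.null(peaks) && nrow(peaks) > 0) {
        heights <- peaks$mean_intensity *
          pmax(0, 1 + stats::rnorm(nrow(peaks), 0, peaks$cv))
        for (p in seq_len(nrow(peaks))) {
          s <- add_peak(s, peaks$mz[p], heights[p])
        }
      }
      s <- s * tic_factor + baseline
      if (spec$noise_sd > 0) s <- s + stats::rnorm(n_mz, 0, spec$noise_sd)
      pmax(s, 0)
    })
    intens[i, ] <- spectrum
  }

  ds <- msi_dataset(
    coords = grid[, c("x", "y")],
    mz = axis, intensities = intens, mode = "continuous",
    patient_id = patient_id,
    condition = {
      tumor <- setdiff(unique(grid$label), c("background", "stroma"))
      if (length(tumor) == 1) tumor else NULL
    },
    pixel_labels = grid$label
  )
  attr(ds, "histomol_truth") <- grid
  ds
}

#' Generate a phantom cohort for classification benchmarks
#'
#' One phantom per patient with patient-to-patient variation: each
#' patient's signature peak means are modulated by a log-normal factor
#' (biological heterogeneity between tumors of the same subtype).
#'
#' @param n_per_class named integer vector of patients per class, e.g.
#'   `c(ccRCC = 9, RO = 9, ChRCC = 5)`.
#' @param seed master seed; patient phantoms draw derived seeds.
#' @param patient_effect_cv CV of the per-patient signature modulation.
#' @param signature_peaks,shared_peaks peak tables as in
#'   [msi_phantom_spec()].
#' @param ... further arguments passed to [msi_phantom_spec()]
#'   (grid size, noise, etc.).
#' @return list of [msi_dataset()]s, one per patient, with `patient_id`
#'   `"P01"`, `"P02"`, ... and `condition` set to the class.
#' @export
generate_msi_cohort <- function(n_per_class = c(ccRCC = 9, RO = 9, ChRCC = 5),
                                seed = 1, patient_effect_cv = 0.1,
                                signature_peaks = default_signature_peaks(),
                                shared_peaks = default_shared_peaks(), ...) {
  classes <- rep(names(n_per_class), n_per_class)
  cohort <- vector("list", length(classes))
  sdlog <- sqrt(log(1 + patient_effect_cv^2))
  for (i in seq_along(classes)) {
    cls <- classes[i]
    pid <- sprintf("P%02d", i)
    patient_sigs <- signature_peaks
    if (patient_effect_cv > 0) {
      patient_sigs[[cls]]$mean_intensity <-
        patient_sigs[[cls]]$mean_intensity * with_seed(
          derive_seed(seed, "patient-effect", i),
          exp(stats::rnorm(nrow(patient_sigs[[cls]]), -sdlog^2 / 2, sdlog))
        )
    }
    spec <- msi_phantom_spec(
      tumor_class = cls,
      class_signature_peaks = patient_sigs,
      shared_peaks = shared_peaks,
      seed = derive_seed(seed, "phantom", i),
      ...
    )
    cohort[[i]] <- generate_msi_phantom(spec, patient_id = pid)
  }
  names(cohort) <- vapply(cohort, function(d) d$metadata$patient_id, character(1))
  cohort
}

#' Recover ground truth from a synthetic object
#'
#' Returns the per-pixel region labels of a phantom MSI dataset, or the
#' per-protein true effects and per-sample classes of a synthetic protein
#' table. Only objects produced by this package's generators carry ground
#' truth; anything else is an error.
#'
#' @param x a phantom [msi_dataset()] or synthetic protein table.
#' @return for phantoms, a data.frame (x, y, label); for protein tables, a
#'   list with `protein_truth` and `sample_truth` data.frames.
#' @export
ground_truth <- function(x) {
  truth <- attr(x, "histomol_truth")
  if (is.null(truth)) {
    stopf("object carries no ground truth (not produced by the synthetic module)")
  }
  truth
}

#' Write a phantom's ground-truth mask as TSV
#'
#' Plain (x, y, label) table, the stand-in for an HE-stain tumor
#' annotation.
#'
#' @param dataset a phantom [msi_dataset()].
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
write_truth_mask <- function(dataset, path) {
  utils::write.table(ground_truth(dataset), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
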