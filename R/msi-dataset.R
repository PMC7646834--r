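#' In-memory mass spectrometry imaging dataset
#'
#' Container for one MSI acquisition: pixel coordinates, per-pixel spectra
#' and patient/condition metadata. Two storage modes mirror the imzML
#' access types: `"continuous"` (all pixels share one m/z axis; intensities
#' held as a pixels x m/z matrix) and `"processed"` (per-pixel m/z axes;
#' intensities held as lists).
#'
#' Coordinates are 1-based, as stored in imzML, and are never re-origined.
#'
#' @param coords data.frame with integer columns `x`, `y`; rows must be
#'   unique pixel positions.
#' @param mz numeric vector (continuous mode) or list of numeric vectors
#'   (processed mode); each axis must be strictly increasing.
#' @param intensities numeric matrix `nrow(coords) x length(mz)`
#'   (continuous) or list of numeric vectors matching `mz` (processed);
#'   all values must be non-negative.
#' @param mode `"continuous"` or `"processed"`.
#' @param patient_id optional patient identifier.
#' @param condition optional pathology label (one of [tumor_classes()] or
#'   any string).
#' @param pixel_labels optional character vector of per-pixel ground-truth
#'   region labels (used by the synthetic phantoms).
#' @return object of class `msi_dataset`.
#' @export
msi_dataset <- function(coords, mz, intensities,
                        mode = c("continuous", "processed"),
                        patient_id = NULL, condition = NULL,
                        pixel_labels = NULL) {
  mode <- match.arg(mode)
  coords <- as.data.frame(coords)
  if (!all(c("x", "y") %in% names(coords))) {
    stopf("coords must have columns 'x' and 'y'")
  }
  coords$x <- as.integer(coords$x)
  coords$y <- as.integer(coords$y)
  if (anyDuplicated(coords[, c("x", "y")])) {
    stopf("pixel coordinates must be unique")
  }
  n <- nrow(coords)
  if (mode == "continuous") {
    mz <- as.numeric(mz)
    if (is.unsorted(mz, strictly = TRUE)) stopf("m/z axis must be strictly increasing")
    intensities <- as.matrix(intensities)
    if (nrow(intensities) != n || ncol(intensities) != length(mz)) {
      stopf("intensities must be a %d x %d matrix", n, length(mz))
    }
    if (any(intensities < 0)) stopf("intensities must be non-negative")
  } else {
    if (!is.list(mz) || !is.list(intensities) ||
        length(mz) != n || length(intensities) != n) {
      stopf("processed mode requires per-pixel lists of length %d", n)
    }
    for (i in seq_len(n)) {
      if (is.unsorted(mz[[i]], strictly = TRUE)) {
        stopf("m/z axis of pixel %d must be strictly increasing", i)
      }
      if (length(mz[[i]]) != length(intensities[[i]])) {
        stopf("pixel %d: axis and intensity lengths differ", i)
      }
      if (any(intensities[[i]] < 0)) stopf("pixel %d has negative intensity", i)
    }
  }
  if (!is.null(pixel_labels) && length(pixel_labels) != n) {
    stopf("pixel_labels must have one entry per pixel")
  }
  structure(
    list(
      coords = coords, mz = mz, intensities = intensities, mode = mode,
      metadata = list(patient_id = patient_id, condition = condition),
      pixel_labels = pixel_labels
    ),
    class = "msi_dataset"
  )
}

#' @export
print.msi_dataset <- function(x, ...) {
  rng <- mz_range(x)
  cat(sprintf(
    "<msi_dataset> %d pixels, mode=%s, m/z %.2f-%.2f%s%s\n",
    n_pixels(x), x$mode, rng[1], rng[2],
    if (!is.null(x$metadata$patient_id)) paste0(", patient=", x$metadata$patient_id) else "",
    if (!is.null(x$metadata$condition)) paste0(", condition=", x$metadata$condition) else ""
  ))
  invisible(x)
}

#' Number of pixels in an MSI dataset
#' @param dataset an [msi_dataset()].
#' @return integer pixel count.
#' @export
n_pixels <- function(dataset) nrow(dataset$coords)

#' Acquired m/z range of an MSI dataset
#' @param dataset an [msi_dataset()].
#' @return numeric length-2 vector (min, max).
#' @export
mz_range <- function(dataset) {
  if (dataset$mode == "continuous") range(dataset$mz)
  else range(unlist(lapply(dataset$mz, range)))
}

# Spectrum of pixel i as list(mz, intensity), regardless of storage mode.
get_spectrum <- function(dataset, i) {
  if (dataset$mode == "continuous") {
    list(mz = dataset$mz, intensity = dataset$intensities[i, ])
  } else {
    list(mz = dataset$mz[[i]], intensity = dataset$intensities[[i]])
  }
}

#' Extract a subset of pixels from an MSI dataset
#'
#' Subsets a dataset to the pixels named in a coordinate mask, preserving
#' pixel order (order of the dataset, not of the mask) and all metadata.
#' This is the step that pulls tumor-cluster pixels out of the unprocessed
#' file once segmentation has delineated them.
#'
#' @param dataset an [msi_dataset()].
#' @param mask data.frame with columns `x`, `y`; every coordinate must be a
#'   pixel of `dataset` and the mask must be non-empty (downstream stages
#'   require at least one pixel).
#' @return an `msi_dataset` with `nrow(mask)` pixels.
#' @export
extract_pixels <- function(dataset, mask) {
  mask <- as.data.frame(mask)
  if (nrow(mask) == 0) stopf("mask is empty: downstream stages require >= 1 pixel")
  key <- paste(dataset$coords$x, dataset$coords$y)
  mkey <- unique(paste(as.integer(mask$x), as.integer(mask$y)))
  missing <- setdiff(mkey, key)
  if (length(missing) > 0) {
    stopf("mask coordinate (%s) is not a pixel of the dataset",
          sub(" ", ", ", missing[1]))
  }
  idx <- which(key %in% mkey)
  msi_dataset(
    coords = dataset$coords[idx, , drop = FALSE],
    mz = if (dataset$mode == "continuous") dataset$mz else dataset$mz[idx],
    intensities = if (dataset$mode == "continuous") {
      dataset$intensities[idx, , drop = FALSE]
    } else {
      dataset$intensities[idx]
    },
    mode = dataset$mode,
    patient_id = dataset$metadata$patient_id,
    condition = dataset$metadata$condition,
    pixel_labels = if (!is.null(dataset$pixel_labels)) dataset$pixel_labels[idx]
  )
}
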