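# Spectral preprocessing: baseline subtraction, TIC normalization, peak
# picking/alignment, and resampling onto common feature axes.

# O(n) centered rolling minimum (van Herk/Gil-Werman): block-wise forward
# and backward cumulative minima combined over a window of `k` points.
rolling_min <- function(x, k) {
  n <- length(x)
  if (k <= 1) return(x)
  if (k %% 2 == 0) k <- k + 1
  half <- (k - 1) %/% 2
  pad <- c(rep(x[1], half), x, rep(x[n], half))
  m <- length(pad)
  n_blocks <- ceiling(m / k)
  padded <- c(pad, rep(Inf, n_blocks * k - m))
  blocks <- matrix(padded, nrow = k)
  fwd <- apply(blocks, 2, cummin)
  bwd <- apply(blocks[k:1, , drop = FALSE], 2, cummin)[k:1, , drop = FALSE]
  fwd <- as.vector(fwd); bwd <- as.vector(bwd)
  lo <- seq_len(m)          # window start in padded coordinates
  hi <- lo + k - 1          # window end (padded array is long enough)
  pmin(bwd[lo], fwd[hi])[seq_len(n)]
}

# Moving-average smoothing with edge padding.
moving_average <- function(x, k) {
  if (k <= 1) return(x)
  if (k %% 2 == 0) k <- k + 1
  half <- (k - 1) %/% 2
  pad <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(pad, rep(1 / k, k), sides = 2))[
    (half + 1):(half + length(x))]
}

#' Subtract a rolling-minimum baseline from a spectrum
#'
#' The baseline is the rolling minimum of the intensities over a window of
#' `2 * half_window` Da, smoothed by a moving average of the same width
#' and capped at the original signal, so the result is non-negative and
#' never exceeds the input. A window much wider than the peak width leaves
#' peak heights essentially untouched while removing slowly varying
#' chemical background.
#'
#' @param intensity numeric intensity vector.
#' @param mz m/z axis of the spectrum (strictly increasing).
#' @param half_window baseline window half width in Da; must be positive
#'   and smaller than the axis span.
#' @return baseline-subtracted intensities (same length).
#' @export
subtract_baseline <- function(intensity, mz, half_window) {
  if (half_window <= 0) stopf("half_window must be > 0")
  span <- mz[length(mz)] - mz[1]
  if (2 * half_window > span) {
    stopf("baseline window (2 x %.3g Da) is wider than the axis span (%.3g Da)",
          half_window, span)
  }
  step <- stats::median(diff(mz))
  k <- max(3L, 2L * ceiling(half_window / step) + 1L)
  n <- length(intensity)
  d <- max(1L, k %/% 40L)  # baseline evaluated at block resolution
  if (d == 1L) {
    base <- moving_average(rolling_min(intensity, k), k)
  } else {
    nb <- ceiling(n / d)
    pad <- c(intensity, rep(intensity[n], nb * d - n))
    block_min <- apply(matrix(pad, nrow = d), 2, min)
    kb <- max(3L, 2L * ceiling(k / (2 * d)) + 1L)
    coarse <- moving_average(rolling_min(block_min, kb), kb)
    centers <- (seq_len(nb) - 0.5) * d + 0.5
    base <- stats::approx(centers, coarse, xout = seq_len(n), rule = 2)$y
  }
  base <- pmin(base, intensity)
  pmax(intensity - base, 0)
}

#' Apply baseline subtraction to every pixel of an MSI dataset
#'
#' @param dataset an [msi_dataset()].
#' @param half_window baseline window half width in Da (default 50).
#' @return an [msi_dataset()] with corrected spectra.
#' @export
subtract_baseline_msi <- function(dataset, half_window = 50) {
  if (dataset$mode == "continuous") {
    out <- dataset
    for (i in seq_len(n_pixels(dataset))) {
      out$intensities[i, ] <-
        subtract_baseline(dataset$intensities[i, ], dataset$mz, half_window)
    }
    out
  } else {
    out <- dataset
    for (i in seq_len(n_pixels(dataset))) {
      out$intensities[[i]] <-
        subtract_baseline(dataset$intensities[[i]], dataset$mz[[i]], half_window)
    }
    out
  }
}

#' Total ion current normalization
#'
#' Scales every spectrum (or matrix row) so all intensity sums are equal.
#' The default target is the dataset-mean TIC, which keeps values in
#' instrument-like units; a plain numeric vector is scaled to
#' `target_sum = 1` by default. Idempotent: normalizing twice changes
#' nothing.
#'
#' @param x an [msi_dataset()], a [feature_matrix()], a numeric matrix
#'   (rows = spectra) or a numeric vector.
#' @param target_sum post-normalization sum; `NULL` means the mean TIC
#'   (vector input: 1).
#' @return same shape as the input.
#' @export
tic_normalize <- function(x, target_sum = NULL) {
  UseMethod("tic_normalize")
}

#' @export
tic_normalize.default <- function(x, target_sum = NULL) {
  if (is.matrix(x)) return(tic_normalize_matrix(x, target_sum, rownames(x)))
  s <- sum(x)
  if (s <= 0) stopf("cannot TIC-normalize an all-zero spectrum")
  if (is.null(target_sum)) target_sum <- 1
  x * (target_sum / s)
}

tic_normalize_matrix <- function(values, target_sum, ids) {
  sums <- rowSums(values)
  if (any(sums <= 0)) {
    bad <- which(sums <= 0)[1]
    stopf("cannot TIC-normalize all-zero spectrum '%s'",
          if (!is.null(ids)) ids[bad] else as.character(bad))
  }
  if (is.null(target_sum)) target_sum <- mean(sums)
  values * (target_sum / sums)
}

#' @export
tic_normalize.msi_dataset <- function(x, target_sum = NULL) {
  if (x$mode == "continuous") {
    ids <- paste0("(", x$coords$x, ", ", x$coords$y, ")")
    x$intensities <- tic_normalize_matrix(x$intensities, target_sum, ids)
  } else {
    sums <- vapply(x$intensities, sum, numeric(1))
    if (any(sums <= 0)) {
      bad <- which(sums <= 0)[1]
      stopf("cannot TIC-normalize all-zero spectrum at pixel (%d, %d)",
            x$coords$x[bad], x$coords$y[bad])
    }
    if (is.null(target_sum)) target_sum <- mean(sums)
    x$intensities <- lapply(seq_along(x$intensities), function(i) {
      x$intensities[[i]] * (target_sum / sums[i])
    })
  }
  x
}

#' @export
tic_normalize.feature_matrix <- function(x, target_sum = NULL) {
  x$values <- tic_normalize_matrix(x$values, target_sum, x$row_ids)
  x
}

#' Peak list
#'
#' Result of peak picking and alignment: peaks with m/z, a representative
#' intensity and signal-to-noise ratio, the number of spectra they were
#' collected from, and the alignment tolerance (NA before alignment).
#'
#' @param peaks data.frame with columns `mz`, `intensity`, `snr`, sorted
#'   by ascending m/z.
#' @param source_pixel_count number of spectra peaks were picked from.
#' @param tolerance alignment tolerance in Da (NA if unaligned).
#' @return object of class `peak_list`.
#' @export
peak_list <- function(peaks, source_pixel_count, tolerance = NA_real_) {
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) > 0) {
    if (is.unsorted(peaks$mz)) peaks <- peaks[order(peaks$mz), , drop = FALSE]
    if (any(peaks$snr < 0, na.rm = TRUE)) stopf("snr must be >= 0")
  }
  structure(list(peaks = peaks, source_pixel_count = source_pixel_count,
                 tolerance = tolerance),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> %d peaks from %d spectra%s\n",
              nrow(x$peaks), x$source_pixel_count,
              if (!is.na(x$tolerance)) sprintf(", aligned at %.3g Da", x$tolerance)
              else ""))
  invisible(x)
}

#' Pick peaks in every stride-th spectrum of an MSI dataset
#'
#' Local intensity maxima with signal-to-noise ratio at least `snr_min`
#' are collected from the pixels at indices 1, 1 + stride, 1 + 2 stride,
#' ... Noise is estimated per spectrum as the scaled median absolute
#' deviation (1.4826 x MAD) of its intensities. The result is an
#' unaligned peak list; run [align_peaks()] before using it as a
#' resampling reference.
#'
#' @param dataset a non-empty [msi_dataset()].
#' @param stride spectrum sampling stride (default 10, i.e. every 10th
#'   spectrum).
#' @param snr_min minimum signal-to-noise ratio (must be > 0; default 3).
#' @return a [peak_list()].
#' @export
pick_peaks <- function(dataset, stride = 10, snr_min = 3) {
  if (n_pixels(dataset) == 0) stopf("dataset is empty")
  if (!is_count(stride, 1)) stopf("stride must be a positive integer")
  if (snr_min <= 0) stopf("snr_min must be > 0")
  idx <- seq(1, n_pixels(dataset), by = stride)
  out <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    sp <- get_spectrum(dataset, idx[j])
    y <- sp$intensity
    n <- length(y)
    noise <- stats::mad(y)
    is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                  y[2:(n - 1)] >= y[3:n], FALSE) & y > 0
    snr <- if (noise > 0) y / noise else ifelse(y > 0, Inf, 0)
    keep <- is_max & snr >= snr_min
    if (any(keep)) {
      out[[j]] <- data.frame(mz = sp$mz[keep], intensity = y[keep],
                             snr = snr[keep])
    }
  }
  peaks <- do.call(rbind, out)
  if (is.null(peaks)) peaks <- data.frame(mz = numeric(0),
                                          intensity = numeric(0),
                                          snr = numeric(0))
  peak_list(peaks, source_pixel_count = length(idx))
}

#' Align a peak list by greedy merging in ascending m/z
#'
#' Walks the m/z-sorted peaks left to right; a peak joins the current
#' group while it lies within `tolerance` of the group's running
#' intensity-weighted mean m/z, otherwise it starts a new group. Each
#' group becomes one peak at the weighted mean m/z with the group's mean
#' intensity and SNR. The output satisfies the minimum-separation
#' invariant (no two peaks closer than `tolerance`).
#'
#' @param peaklist a [peak_list()].
#' @param tolerance merge tolerance in Da (> 0).
#' @return an aligned [peak_list()].
#' @export
align_peaks <- function(peaklist, tolerance = 0.25) {
  if (tolerance <= 0) stopf("tolerance must be > 0")
  pk <- peaklist$peaks
  if (nrow(pk) == 0) return(peak_list(pk, peaklist$source_pixel_count, tolerance))
  pk <- pk[order(pk$mz), , drop = FALSE]
  group <- integer(nrow(pk))
  g <- 1L
  group[1] <- g
  wsum <- pk$intensity[1]
  wmz <- pk$mz[1] * pk$intensity[1]
  for (i in seq_len(nrow(pk))[-1]) {
    center <- if (wsum > 0) wmz / wsum else pk$mz[i - 1]
    if (pk$mz[i] - center <= tolerance) {
      group[i] <- g
      wsum <- wsum + pk$intensity[i]
      wmz <- wmz + pk$mz[i] * pk$intensity[i]
    } else {
      g <- g + 1L
      group[i] <- g
      wsum <- pk$intensity[i]
      wmz <- pk$mz[i] * pk$intensity[i]
    }
  }
  merged <- do.call(rbind, lapply(split(pk, group), function(d) {
    w <- d$intensity
    if (sum(w) == 0) w <- rep(1, nrow(d))
    data.frame(mz = sum(d$mz * w) / sum(w),
               intensity = mean(d$intensity), snr = mean(d$snr),
               count = nrow(d))
  }))
  merged <- merged[order(merged$mz), , drop = FALSE]
  rownames(merged) <- NULL
  peak_list(merged, peaklist$source_pixel_count, tolerance)
}

#' Filter aligned peaks by recurrence across spectra
#'
#' Keeps the peaks whose merged group contains picks from at least
#' `min_freq` of the sampled spectra. Genuine tissue peaks recur across
#' many spectra whereas noise maxima are picked once; frequency
#' filtering is the standard way to separate the two after alignment.
#'
#' @param peaklist an aligned [peak_list()] (needs the `count` column
#'   produced by [align_peaks()]).
#' @param min_freq minimum fraction of source spectra (default 0.1).
#' @return the filtered [peak_list()].
#' @export
filter_peak_frequency <- function(peaklist, min_freq = 0.1) {
  if (is.null(peaklist$peaks$count)) {
    stopf("peak list has no recurrence counts; align it first")
  }
  keep <- peaklist$peaks$count >= min_freq * peaklist$source_pixel_count
  peak_list(peaklist$peaks[keep, , drop = FALSE],
            peaklist$source_pixel_count, peaklist$tolerance)
}

# Row provenance shared by the two resamplers.
msi_row_groups <- function(dataset) {
  data.frame(
    x = dataset$coords$x, y = dataset$coords$y,
    patient_id = if (is.null(dataset$metadata$patient_id)) NA_character_
                 else dataset$metadata$patient_id,
    condition = if (is.null(dataset$metadata$condition)) NA_character_
                else dataset$metadata$condition,
    stringsAsFactors = FALSE
  )
}

msi_row_ids <- function(dataset) {
  prefix <- if (is.null(dataset$metadata$patient_id)) "px"
            else dataset$metadata$patient_id
  paste0(prefix, "_", dataset$coords$x, "_", dataset$coords$y)
}

#' Resample spectra to a reference peak list by window maxima
#'
#' "Height" resampling: the value of (pixel, reference peak) is the
#' maximum intensity within `tolerance` of the reference m/z in that
#' pixel's spectrum, or 0 when no point falls inside the window.
#'
#' @param dataset a non-empty [msi_dataset()].
#' @param reference an aligned, non-empty [peak_list()].
#' @param tolerance window half width in Da (default 0.125, half the
#'   0.25 Da resampling step).
#' @return a [feature_matrix()] with the reference m/z as feature axis.
#' @export
resample_height <- function(dataset, reference, tolerance = 0.125) {
  if (n_pixels(dataset) == 0) stopf("dataset is empty")
  mzs <- reference$peaks$mz
  if (length(mzs) == 0) stopf("reference peak list is empty")
  n <- n_pixels(dataset)
  vals <- matrix(0, n, length(mzs))
  for (i in seq_len(n)) {
    sp <- get_spectrum(dataset, i)
    lo <- findInterval(mzs - tolerance, sp$mz) + 1
    hi <- findInterval(mzs + tolerance, sp$mz)
    for (j in seq_along(mzs)) {
      if (lo[j] <= hi[j]) vals[i, j] <- max(sp$intensity[lo[j]:hi[j]])
    }
  }
  feature_matrix(vals, mzs, msi_row_ids(dataset), msi_row_groups(dataset))
}

#' Resample spectra onto a regular m/z grid
#'
#' Linear interpolation of each spectrum at the grid points
#' `mz_min, mz_min + step, ..., mz_max` (endpoints inclusive; the default
#' 700-2500 Da at 0.25 Da gives 7201 features), 0 outside the spectrum's
#' support. This is the restriction-and-resampling step that puts all
#' patients on one common feature axis.
#'
#' @param dataset a non-empty [msi_dataset()].
#' @param mz_min,mz_max grid range in Da (min < max).
#' @param step grid step in Da (> 0).
#' @return a [feature_matrix()] with the grid as feature axis.
#' @export
bin_resample <- function(dataset, mz_min = 700, mz_max = 2500, step = 0.25) {
  if (mz_min >= mz_max) stopf("mz_min must be < mz_max")
  if (step <= 0) stopf("step must be > 0")
  if (n_pixels(dataset) == 0) stopf("dataset is empty")
  grid <- seq(mz_min, mz_max, by = step)
  n <- n_pixels(dataset)
  vals <- matrix(0, n, length(grid))
  for (i in seq_len(n)) {
    sp <- get_spectrum(dataset, i)
    vals[i, ] <- stats::approx(sp$mz, sp$intensity, xout = grid,
                               method = "linear", yleft = 0, yright = 0)$y
  }
  feature_matrix(vals, grid, msi_row_ids(dataset), msi_row_groups(dataset))
}
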