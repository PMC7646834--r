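#' Feature matrix of pixels or samples by spectral/protein features
#'
#' Uniform container for resampled MSI pixel intensities (numeric m/z
#' feature axis) or protein abundances (character feature axis), with row
#' provenance (pixel coordinates, patient, condition).
#'
#' @param values numeric matrix, rows = pixels/samples, columns = features.
#' @param feature_axis numeric (strictly increasing m/z grid) or character
#'   (protein ids), one entry per column.
#' @param row_ids unique row identifiers.
#' @param row_groups data.frame of row annotations (e.g. `x`, `y`,
#'   `patient_id`, `condition`), one row per matrix row; may be `NULL`.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, feature_axis, row_ids, row_groups = NULL) {
  values <- as.matrix(values)
  if (length(feature_axis) != ncol(values)) {
    stopf("feature_axis length must equal the number of columns")
  }
  if (is.numeric(feature_axis)) {
    if (is.unsorted(feature_axis, strictly = TRUE)) {
      stopf("numeric feature axis must be strictly increasing")
    }
    if (any(values < 0)) stopf("MSI intensities must be non-negative")
  }
  if (length(row_ids) != nrow(values)) stopf("one row id per row required")
  if (anyDuplicated(row_ids)) stopf("row ids must be unique")
  if (!is.null(row_groups)) {
    row_groups <- as.data.frame(row_groups)
    if (nrow(row_groups) != nrow(values)) {
      stopf("row_groups must have one row per matrix row")
    }
  }
  rownames(values) <- row_ids
  structure(
    list(values = values, feature_axis = feature_axis,
         row_ids = row_ids, row_groups = row_groups),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d rows x %d features (%s axis)\n",
              nrow(x$values), ncol(x$values),
              if (is.numeric(x$feature_axis)) "m/z" else "id"))
  invisible(x)
}

#' Stack feature matrices sharing one feature axis
#'
#' Row-binds per-patient matrices (e.g. per-patient resampled MSI data)
#' into one matrix; the feature axes must be identical.
#'
#' @param matrices list of [feature_matrix()] objects.
#' @return a single [feature_matrix()].
#' @export
bind_feature_matrices <- function(matrices) {
  if (length(matrices) == 0) stopf("no matrices to bind")
  axis <- matrices[[1]]$feature_axis
  for (m in matrices[-1]) {
    if (!isTRUE(all.equal(m$feature_axis, axis))) {
      stopf("feature axes differ; resample to a common axis first")
    }
  }
  feature_matrix(
    values = do.call(rbind, lapply(matrices, `[[`, "values")),
    feature_axis = axis,
    row_ids = unlist(lapply(matrices, `[[`, "row_ids")),
    row_groups = do.call(rbind, lapply(matrices, `[[`, "row_groups"))
  )
}
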