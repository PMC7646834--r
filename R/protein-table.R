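#' Protein quantification table
#'
#' Label-free quantification matrix (proteins x extraction-spot samples)
#' with per-protein flag columns and per-sample design metadata, the
#' in-memory form of a MaxQuant proteinGroups-style export. Missing
#' quantifications are explicit `NA`s (raw zeros in input files are
#' treated as missing). The `scale` field tracks whether values are raw
#' LFQ intensities or log2-transformed, so transforms cannot be applied
#' twice.
#'
#' @param protein_ids character vector of protein (group) identifiers.
#' @param intensities numeric matrix, rows = proteins, columns = samples;
#'   raw-scale values must be positive where present.
#' @param sample_meta data.frame with columns `sample_id`, `patient_id`,
#'   `class`, `spot_id` (one row per column of `intensities`).
#' @param flags data.frame with logical columns `contaminant`, `reverse`,
#'   `only_by_site` (one row per protein); defaults to all-FALSE.
#' @param scale `"raw"` or `"log2"`.
#' @return object of class `protein_quant_table`.
#' @export
protein_quant_table <- function(protein_ids, intensities, sample_meta,
                                flags = NULL, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  intensities <- as.matrix(intensities)
  n <- length(protein_ids)
  if (anyDuplicated(protein_ids)) stopf("protein ids must be unique")
  if (nrow(intensities) != n) stopf("one intensity row per protein required")
  sample_meta <- as.data.frame(sample_meta)
  req <- c("sample_id", "patient_id", "class", "spot_id")
  if (!all(req %in% names(sample_meta))) {
    stopf("sample_meta needs columns: %s", paste(req, collapse = ", "))
  }
  if (nrow(sample_meta) != ncol(intensities)) {
    stopf("one sample_meta row per intensity column required")
  }
  if (anyDuplicated(sample_meta$sample_id)) stopf("sample ids must be unique")
  if (is.null(flags)) {
    flags <- data.frame(contaminant = logical(n), reverse = logical(n),
                        only_by_site = logical(n))
  }
  flags <- as.data.frame(flags)
  for (f in c("contaminant", "reverse", "only_by_site")) {
    if (!f %in% names(flags)) flags[[f]] <- logical(n)
    if (!is.logical(flags[[f]])) stopf("flag column '%s' must be logical", f)
  }
  if (scale == "raw" && any(intensities <= 0, na.rm = TRUE)) {
    bad <- which(intensities <= 0, arr.ind = TRUE)[1, ]
    stopf("raw intensities must be positive where present (protein %s, sample %s)",
          protein_ids[bad[1]], sample_meta$sample_id[bad[2]])
  }
  rownames(intensities) <- protein_ids
  colnames(intensities) <- sample_meta$sample_id
  structure(
    list(protein_ids = protein_ids, intensities = intensities,
         sample_meta = sample_meta, flags = flags, scale = scale),
    class = "protein_quant_table"
  )
}

#' @export
print.protein_quant_table <- function(x, ...) {
  cat(sprintf(
    "<protein_quant_table> %d proteins x %d samples (%s scale), %.1f%% missing\n",
    nrow(x$intensities), ncol(x$intensities), x$scale,
    100 * mean(is.na(x$intensities))
  ))
  invisible(x)
}

n_samples <- function(table) ncol(table$intensities)

# Subset a protein table by protein row index, keeping everything in step.
subset_proteins <- function(table, idx) {
  out <- table
  out$protein_ids <- table$protein_ids[idx]
  out$intensities <- table$intensities[idx, , drop = FALSE]
  out$flags <- table$flags[idx, , drop = FALSE]
  truth <- attr(table, "histomol_truth")
  if (!is.null(truth)) {
    truth$protein_truth <-
      truth$protein_truth[truth$protein_truth$protein_id %in% out$protein_ids, ]
    attr(out, "histomol_truth") <- truth
  }
  out
}

#' Write a protein table in the proteinGroups TSV dialect
#'
#' Columns: `Majority protein IDs`, one `LFQ intensity <sample>` column
#' per sample (missing written as 0, the MaxQuant convention), and the
#' `Only identified by site` / `Reverse` / `Potential contaminant` flag
#' columns marked with `+`. A companion metadata TSV (sample, patient,
#' class, spot) is written next to it.
#'
#' @param table a raw-scale [protein_quant_table()].
#' @param path output TSV path for the quantification table.
#' @param meta_path output TSV path for the sample metadata (default:
#'   `<path>` with `_metadata.tsv` suffix).
#' @return invisibly, a list of the two paths.
#' @export
write_protein_table <- function(table, path,
                                meta_path = sub("\\.tsv$", "_metadata.tsv", path)) {
  if (table$scale != "raw") stopf("only raw-scale tables are written to disk")
  vals <- table$intensities
  vals[is.na(vals)] <- 0
  df <- data.frame(`Majority protein IDs` = table$protein_ids,
                   check.names = FALSE)
  for (j in seq_len(ncol(vals))) {
    df[[paste("LFQ intensity", colnames(vals)[j])]] <- vals[, j]
  }
  df[["Only identified by site"]] <- ifelse(table$flags$only_by_site, "+", "")
  df[["Reverse"]] <- ifelse(table$flags$reverse, "+", "")
  df[["Potential contaminant"]] <- ifelse(table$flags$contaminant, "+", "")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- table$sample_meta
  colnames(meta)[colnames(meta) == "sample_id"] <- "sample"
  colnames(meta)[colnames(meta) == "patient_id"] <- "patient"
  colnames(meta)[colnames(meta) == "spot_id"] <- "spot"
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(table = path, metadata = meta_path))
}

#' Read a proteinGroups-style TSV plus sample metadata
#'
#' Inverse of [write_protein_table()]: `LFQ intensity <sample>` columns
#' become the intensity matrix (zeros read as missing), `+` marks in the
#' flag columns become logical flags.
#'
#' @param path proteinGroups-style TSV.
#' @param meta_path metadata TSV with columns sample, patient, class, spot.
#' @return a raw-scale [protein_quant_table()].
#' @export
read_protein_table <- function(path,
                               meta_path = sub("\\.tsv$", "_metadata.tsv", path)) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  lfq_cols <- grep("^LFQ intensity ", names(df), value = TRUE)
  sample_ids <- sub("^LFQ intensity ", "", lfq_cols)
  vals <- as.matrix(df[, lfq_cols, drop = FALSE])
  colnames(vals) <- sample_ids
  vals[vals == 0] <- NA
  flag <- function(col) {
    if (col %in% names(df)) !is.na(df[[col]]) & df[[col]] == "+" else rep(FALSE, nrow(df))
  }
  meta <- meta[match(sample_ids, meta$sample), ]
  protein_quant_table(
    protein_ids = df[["Majority protein IDs"]],
    intensities = vals,
    sample_meta = data.frame(sample_id = meta$sample,
                             patient_id = meta$patient,
                             class = meta$class, spot_id = meta$spot,
                             stringsAsFactors = FALSE),
    flags = data.frame(contaminant = flag("Potential contaminant"),
                       reverse = flag("Reverse"),
                       only_by_site = flag("Only identified by site")),
    scale = "raw"
  )
}
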