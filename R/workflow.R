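# End-to-end orchestration: configuration, seeding, the two analysis
# tracks and the synthetic benchmark.

#' Workflow configuration
#'
#' All tunable parameters of both tracks with their study defaults:
#' margin rule 0.10, ANOVA FDR 0.01, 70% valid-value filter, k = 5 RBF
#' SVM, classification feature axis m/z 700-2500 at 0.25 Da, component
#' search capped at 34. A single master seed deterministically derives
#' every stage seed.
#'
#' @param seed master seed.
#' @param margin MSI patient-call margin fraction.
#' @param fdr ANOVA Benjamini-Hochberg FDR threshold.
#' @param min_valid valid-value fraction filter.
#' @param k,kernel,cost SVM cross-validation settings.
#' @param mz_min,mz_max,mz_step classification resampling grid (Da).
#' @param n_components PLS components used for the cohort benchmark.
#' @param max_components cap of the component search.
#' @param baseline_half_window baseline window half width (Da).
#' @param peak_stride,snr_min,align_tolerance,height_tolerance peak
#'   picking/alignment/height-resampling settings.
#' @param seg_k_init,seg_r,seg_s segmentation parameters.
#' @param msi_cohort named patient counts for the MSI phantom cohort.
#' @param proteome_design_args list of [proteome_design()] overrides.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1, margin = 0.10, fdr = 0.01,
                       min_valid = 0.70, k = 5, kernel = "rbf", cost = 10,
                       mz_min = 700, mz_max = 2500, mz_step = 0.25,
                       n_components = 5, max_components = 34,
                       baseline_half_window = 50,
                       peak_stride = 10, snr_min = 6,
                       align_tolerance = 0.25, height_tolerance = 0.125,
                       seg_k_init = 4, seg_r = 1, seg_s = 0,
                       msi_cohort = c(ccRCC = 9, RO = 9, ChRCC = 5),
                       proteome_design_args = list()) {
  cfg <- structure(as.list(environment()), class = "run_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$margin <= 0 || cfg$margin >= 1) stopf("margin must be in (0, 1)")
  if (cfg$fdr <= 0 || cfg$fdr >= 1) stopf("fdr must be in (0, 1)")
  if (cfg$min_valid <= 0 || cfg$min_valid > 1) stopf("min_valid must be in (0, 1]")
  if (!is_count(cfg$k, 2)) stopf("k must be an integer >= 2")
  if (!cfg$kernel %in% c("rbf", "linear")) stopf("kernel must be rbf or linear")
  if (cfg$mz_min >= cfg$mz_max || cfg$mz_step <= 0) stopf("invalid m/z grid")
  if (!is_count(cfg$n_components, 1) || !is_count(cfg$max_components, 1)) {
    stopf("component counts must be positive integers")
  }
  invisible(cfg)
}

write_manifest <- function(dir, config, stage, outputs) {
  cfg_json <- jsonlite::toJSON(config[order(names(config))],
                               auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(
    stage = stage,
    seed = config$seed,
    config_md5 = unname(tools::md5sum(tmp)),
    package_version = as.character(utils::packageVersion("histomol")),
    outputs = outputs
  )
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Process one MSI dataset up to its tumor-pixel feature rows
#'
#' Per-section pipeline: baseline subtraction; peak picking in every
#' stride-th spectrum with alignment; height-resampling onto the peak
#' list; spatially-aware segmentation; tumor-cluster selection against
#' the reference annotation; extraction of the tumor pixels from the
#' unprocessed data; TIC normalization of the extracted pixels; and
#' resampling onto the common classification grid.
#'
#' @param dataset an [msi_dataset()].
#' @param reference_mask data.frame (`x`, `y`) of annotated tumor pixels
#'   (for phantoms: the ground-truth tumor region).
#' @param config a [run_config()].
#' @return list with `features` (the classification [feature_matrix()]
#'   of tumor pixels), `segmentation`, `tumor_pixels`.
#' @export
process_msi_section <- function(dataset, reference_mask, config = run_config()) {
  ds <- subtract_baseline_msi(dataset, config$baseline_half_window)
  peaks <- filter_peak_frequency(
    align_peaks(
      pick_peaks(ds, stride = config$peak_stride, snr_min = config$snr_min),
      tolerance = config$align_tolerance
    ),
    min_freq = 0.1
  )
  seg_features <- resample_height(ds, peaks, tolerance = config$height_tolerance)
  seg <- spatial_shrunken_centroids(
    seg_features,
    params = segmentation_params(k_init = config$seg_k_init, r = config$seg_r,
                                 s = config$seg_s,
                                 seed = derive_seed(config$seed, "seg",
                                                    dataset$metadata$patient_id %||% 0))
  )
  tumor <- select_tumor_clusters(seg, reference_mask, threshold = 0.5,
                                 metric = "precision")
  extracted <- extract_pixels(ds, tumor[, c("x", "y")])
  extracted <- tic_normalize(extracted)
  features <- bin_resample(extracted, config$mz_min, config$mz_max,
                           config$mz_step)
  list(features = features, segmentation = seg, tumor_pixels = tumor)
}

#' Run the MSI track on a phantom cohort
#'
#' Generates (or accepts) a cohort of phantom tissue sections, processes
#' each section ([process_msi_section()]) with its ground-truth tumor
#' annotation as the reference mask, pools the tumor-pixel features on
#' the common m/z grid, runs leave-one-patient-out PLS-DA
#' cross-validation, and produces per-patient margin-rule calls.
#'
#' @param config a [run_config()].
#' @param cohort optional list of phantom [msi_dataset()]s (default:
#'   generated from `config$msi_cohort` and the master seed).
#' @param output_dir optional directory for score-map TSVs, call JSON
#'   and a manifest.
#' @return list: `cv` ([loo_patient_cv()] result), `calls`
#'   (per-patient [patient_call()]s), `patient_accuracy` data.frame,
#'   `features`, `config`.
#' @export
run_msi_track <- function(config = run_config(), cohort = NULL,
                          output_dir = NULL) {
  if (is.null(cohort)) {
    cohort <- generate_msi_cohort(
      n_per_class = config$msi_cohort,
      seed = derive_seed(config$seed, "msi-cohort")
    )
  }
  per_patient <- lapply(cohort, function(ds) {
    truth <- ground_truth(ds)
    tumor_class <- ds$metadata$condition
    mask <- truth[truth$label == tumor_class, c("x", "y")]
    process_msi_section(ds, mask, config)$features
  })
  features <- bind_feature_matrices(per_patient)
  cv <- loo_patient_cv(features, n_components = config$n_components)
  calls <- patient_calls_from_cv(cv, margin_fraction = config$margin)

  truth_by_patient <- vapply(cohort, function(d) d$metadata$condition,
                             character(1))
  patient_accuracy <- data.frame(
    patient_id = names(calls),
    truth = truth_by_patient[names(calls)],
    winner = vapply(calls, `[[`, character(1), "winner"),
    ambiguous = vapply(calls, function(cl) {
      paste(cl$ambiguous_with, collapse = "/")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  patient_accuracy$correct <- patient_accuracy$winner == patient_accuracy$truth

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(cv$pixel_scores,
                       file.path(output_dir, "msi_pixel_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(patient_accuracy,
                       file.path(output_dir, "msi_patient_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(output_dir, config, "msi_track",
                   c("msi_pixel_scores.tsv", "msi_patient_calls.tsv"))
  }
  list(cv = cv, calls = calls, patient_accuracy = patient_accuracy,
       features = features, config = config)
}

#' Run the proteomics track on a synthetic cohort table
#'
#' Pipeline: flag filter, log2 transform, valid-value filter, ANOVA +
#' BH significance filter (on unimputed values), down-shifted normal
#' imputation, then SVM k-fold cross-validation of the extraction-spot
#' samples (sarcomatoid-analog outlier samples excluded from
#' training/testing) and PCA with 95% prediction ellipses for
#' irregularity detection. Patient-level calls aggregate spot scores by
#' mean; a patient is irregular when more than half of their spots fall
#' outside their predicted class's ellipse.
#'
#' @param config a [run_config()].
#' @param table optional raw [protein_quant_table()] with ground truth
#'   (default: generated from `proteome_design` and the master seed).
#' @param output_dir optional output directory.
#' @return list: `cv` report, `radar`, `pca`, `calls` (per-patient
#'   [lcms_call()]s), `diff` (ANOVA result), `table_filtered`, `config`.
#' @export
run_prot_track <- function(config = run_config(), table = NULL,
                           output_dir = NULL) {
  if (is.null(table)) {
    args <- config$proteome_design_args
    args$seed <- derive_seed(config$seed, "prot-cohort")
    table <- generate_protein_table(do.call(proteome_design, args))
  }
  truth <- attr(table, "histomol_truth")

  filtered <- filter_valid(log_transform(filter_flags(table)),
                           config$min_valid)
  diff <- anova_bh(filtered, fdr = config$fdr)
  sig <- filter_significant(filtered, diff)
  imputed <- impute_normal(sig, seed = derive_seed(config$seed, "impute"))

  x <- t(imputed$intensities)  # samples x proteins
  meta <- imputed$sample_meta
  outlier_samples <- if (!is.null(truth)) {
    truth$sample_truth$sample_id[truth$sample_truth$is_outlier]
  } else character(0)
  include <- !meta$sample_id %in% outlier_samples

  cfg <- cv_config(k = config$k, kernel = config$kernel, cost = config$cost,
                   seed = derive_seed(config$seed, "svm"))
  cv <- svm_cv(x[include, , drop = FALSE], meta$class[include], cfg,
               patient_ids = meta$patient_id[include])
  radar <- radar_scores(cv)

  pca <- pca_with_ellipses(x, meta$class)

  # patient-level calls: mean spot score per class; the excluded outlier
  # patient is scored by a model trained on all included samples
  scores <- as.matrix(cv$samples[, cv$class_order, drop = FALSE])
  rownames(scores) <- cv$samples$sample_id
  if (any(!include)) {
    tr <- x[include, , drop = FALSE]
    mu <- colMeans(tr); sd_ <- apply(tr, 2, stats::sd); sd_[sd_ == 0] <- 1
    sc_out <- ovr_svm_scores(
      sweep(sweep(tr, 2, mu), 2, sd_, `/`), meta$class[include],
      sweep(sweep(x[!include, , drop = FALSE], 2, mu), 2, sd_, `/`), cfg
    )
    rownames(sc_out) <- meta$sample_id[!include]
    scores <- rbind(scores, sc_out[, cv$class_order, drop = FALSE])
  }

  # Irregularity rule (b): a patient's spots are tested against the
  # prediction ellipse of their predicted class fitted WITHOUT that
  # patient's own spots, so an aberrant patient cannot widen the region
  # that is supposed to catch it.
  calls <- list()
  pc12 <- pca$scores[, 1:2, drop = FALSE]
  for (pid in unique(meta$patient_id)) {
    sids <- meta$sample_id[meta$patient_id == pid]
    sc <- scores[rownames(scores) %in% sids, , drop = FALSE]
    cls <- cv$class_order[which.max(colMeans(sc))]
    sample_idx <- which(meta$sample_id %in% sids)
    ref_idx <- which(meta$class == cls & meta$patient_id != pid)
    irregular <- FALSE
    if (length(ref_idx) >= 3) {
      ell <- prediction_ellipse(pc12[ref_idx, , drop = FALSE])
      spots_out <- mean(!in_ellipse(pc12[sample_idx, , drop = FALSE], ell))
      centroid_out <- !in_ellipse(colMeans(pc12[sample_idx, , drop = FALSE]),
                                  ell)
      irregular <- spots_out > 0.5 && centroid_out
    }
    calls[[pid]] <- lcms_call(cls, irregular = irregular, patient_id = pid)
  }

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(radar, file.path(output_dir, "prot_radar_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(diff$result,
                       file.path(output_dir, "prot_differential.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(output_dir, config, "prot_track",
                   c("prot_radar_scores.tsv", "prot_differential.tsv"))
  }
  list(cv = cv, radar = radar, pca = pca, calls = calls, diff = diff,
       table_filtered = imputed,
       outlier_patient = if (length(outlier_samples) > 0) {
         unique(meta$patient_id[meta$sample_id %in% outlier_samples])[1]
       } else NA_character_,
       config = config)
}

#' Phantom of the sarcomatoid-like outlier section
#'
#' A tumor whose spectral signature is a half/half mixture of the ChRCC
#' and ccRCC signatures: classified against the clean three-class model
#' it co-scores ccRCC and ChRCC, the irregular pattern the integration
#' stage must flag.
#'
#' @param seed phantom seed.
#' @param weights named mixture weights (default ChRCC/ccRCC 0.5/0.5).
#' @param ... further [msi_phantom_spec()] arguments.
#' @return a phantom [msi_dataset()] with `condition` set to the
#'   dominant mixture class.
#' @export
msi_outlier_phantom <- function(seed = 1,
                                weights = c(ChRCC = 0.5, ccRCC = 0.5),
                                ...) {
  sigs <- default_signature_peaks()
  # convex mixture: each parent signature at its weight's fraction, so
  # the total signal stays at one class's level
  mix <- do.call(rbind, lapply(names(weights), function(cls) {
    s <- sigs[[cls]]
    s$mean_intensity <- s$mean_intensity * weights[[cls]]
    s
  }))
  dominant <- names(weights)[which.max(weights)]
  sigs[[dominant]] <- mix
  generate_msi_phantom(
    msi_phantom_spec(tumor_class = dominant, class_signature_peaks = sigs,
                     seed = seed, ...),
    patient_id = "OUTLIER"
  )
}

#' Run the full synthetic benchmark
#'
#' Executes the MSI track (23-patient phantom cohort), the proteomics
#' track (28-patient synthetic table with the sarcomatoid-analog
#' patient), classifies the sarcomatoid-analog phantom against the MSI
#' cohort model, and integrates the per-patient calls including the
#' published decision-table check.
#'
#' @param config a [run_config()].
#' @param output_dir optional output directory for all artifacts.
#' @return list with `msi`, `prot`, `outlier` (the analog's MSI call and
#'   integrated diagnosis) and `table1` (decision table applied to the
#'   published per-patient columns).
#' @export
run_benchmark <- function(config = run_config(), output_dir = NULL) {
  msi <- run_msi_track(config, output_dir = output_dir)
  prot <- run_prot_track(config, output_dir = output_dir)

  # sarcomatoid analog: model trained on the full clean cohort
  model <- fit_plsda(msi$features$values, msi$features$row_groups$condition,
                     config$n_components)
  outlier_ds <- msi_outlier_phantom(seed = derive_seed(config$seed, "outlier"),
                                    grid_width = 30, grid_height = 30)
  truth <- ground_truth(outlier_ds)
  dominant <- outlier_ds$metadata$condition
  mask <- truth[truth$label == dominant, c("x", "y")]
  out_features <- process_msi_section(outlier_ds, mask, config)$features
  out_scores <- predict(model, out_features$values)
  out_call <- patient_call(out_scores, classes = model$class_order,
                           margin_fraction = config$margin,
                           patient_id = "OUTLIER")
  out_irr <- flag_irregular(out_call)
  outlier_prot_call <- if (!is.na(prot$outlier_patient)) {
    prot$calls[[prot$outlier_patient]]
  } else NULL
  integrated <- integrate_calls(
    msi_call(out_call$winner, out_call$ambiguous_with,
             irregular = out_irr$irregular, patient_id = "OUTLIER"),
    outlier_prot_call %||% lcms_call(dominant)
  )

  table1 <- integrate_table(load_integration_table())

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(table1, file.path(output_dir, "integration_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(output_dir, config, "benchmark", "integration_table.tsv")
  }
  list(msi = msi, prot = prot,
       outlier = list(msi_call = out_call, irregular = out_irr,
                      integrated = integrated),
       table1 = table1)
}
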