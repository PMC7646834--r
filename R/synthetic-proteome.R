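# Synthetic label-free protein quantification tables with known truth.
#
# Generative model on the log2 scale, per protein p and sample s (patient
# q(s), class c(s)):
#
#   log2 x_ps = mu_p + effect_p(c(s)) + patient_dev_pq + spot_noise_ps
#
# with mu_p ~ N(base_mean, base_sd), effect_p(c) = log2fc for proteins
# designed class-specific to c (0 otherwise), patient_dev ~ N(0,
# patient_sd) per protein x patient, spot noise ~ N(0, spot_sd).
# Missingness is MNAR: P(missing | log2 x) = plogis(a + b log2 x) with
# b < 0 so low-abundance values vanish more often. The optional outlier
# patient replaces its class effects by a convex mixture of two class
# profiles, emulating a sarcomatoid transformation that resembles both
# parent classes. Per-protein random streams derive their own seeds so
# dropping proteins never changes the remaining rows.

#' Design of a synthetic proteome quantification experiment
#'
#' Defaults emulate the study scale at desk size: 28 patients
#' (12 ccRCC / 11 RO / 5 ChRCC) with 2-6 extraction spots each, 400
#' quantified proteins of which 10 per class are class-specific, plus
#' flagged contaminant/reverse rows, and one sarcomatoid-like outlier
#' patient inside the ChRCC cohort mixing the ChRCC and ccRCC profiles.
#'
#' @param n_proteins_total total non-flagged protein rows.
#' @param n_class_specific_per_class class-specific proteins per class;
#'   `3 * n_class_specific_per_class` must not exceed the total.
#' @param patients_per_class named integer vector over
#'   [tumor_classes()].
#' @param spots_per_patient_range inclusive (min, max) extraction spots
#'   per patient, within 1..10.
#' @param base_log_intensity_mean,base_log_intensity_sd distribution of
#'   per-protein base log2 intensity.
#' @param class_effect_log2fc log2 fold change of class-specific proteins
#'   in their class.
#' @param spot_noise_sd,patient_noise_sd log2-scale noise SDs.
#' @param missingness_model numeric `c(intercept, slope)` of the logistic
#'   MNAR model on log2 intensity; `c(-Inf, 0)` disables missingness.
#' @param n_contaminant_rows,n_reverse_rows,n_only_site_rows counts of
#'   flagged filler rows.
#' @param outlier_patient `NULL`, or list with `class` (assigned label)
#'   and `weights` (named mixture weights over class profiles summing
#'   to 1); default mixes ChRCC and ccRCC half-and-half.
#' @param seed integer master seed.
#' @return object of class `proteome_design`.
#' @export
proteome_design <- function(n_proteins_total = 400,
                            n_class_specific_per_class = 10,
                            patients_per_class = c(ccRCC = 12, RO = 11, ChRCC = 5),
                            spots_per_patient_range = c(2, 6),
                            base_log_intensity_mean = 24,
                            base_log_intensity_sd = 2,
                            class_effect_log2fc = 2,
                            spot_noise_sd = 0.4,
                            patient_noise_sd = 0.5,
                            missingness_model = c(intercept = 17, slope = -0.8),
                            n_contaminant_rows = 5,
                            n_reverse_rows = 5,
                            n_only_site_rows = 3,
                            outlier_patient = list(
                              class = "ChRCC",
                              weights = c(ChRCC = 0.5, ccRCC = 0.5)
                            ),
                            seed = 1) {
  if (!is_count(n_proteins_total, 0) || !is_count(n_class_specific_per_class, 0)) {
    stopf("protein counts must be non-negative integers")
  }
  if (3 * n_class_specific_per_class > n_proteins_total) {
    stopf("3 x n_class_specific_per_class must not exceed n_proteins_total")
  }
  if (any(patients_per_class < 1)) stopf("every class needs at least one patient")
  if (!all(names(patients_per_class) %in% tumor_classes())) {
    stopf("patients_per_class names must be tumor classes")
  }
  rng <- spots_per_patient_range
  if (length(rng) != 2 || rng[1] > rng[2] || rng[1] < 1 || rng[2] > 10) {
    stopf("spots_per_patient_range must be an increasing pair within [1, 10]")
  }
  if (!is.null(outlier_patient)) {
    w <- outlier_patient$weights
    if (abs(sum(w) - 1) > 1e-8) stopf("outlier mixture weights must sum to 1")
    if (!outlier_patient$class %in% names(patients_per_class)) {
      stopf("outlier class must be one of the cohort classes")
    }
  }
  if (any(c(n_contaminant_rows, n_reverse_rows, n_only_site_rows) < 0)) {
    stopf("flagged row counts must be >= 0")
  }
  structure(
    list(n_proteins_total = n_proteins_total,
         n_class_specific_per_class = n_class_specific_per_class,
         patients_per_class = patients_per_class,
         spots_per_patient_range = rng,
         base_log_intensity_mean = base_log_intensity_mean,
         base_log_intensity_sd = base_log_intensity_sd,
         class_effect_log2fc = class_effect_log2fc,
         spot_noise_sd = spot_noise_sd,
         patient_noise_sd = patient_noise_sd,
         missingness_model = missingness_model,
         n_contaminant_rows = n_contaminant_rows,
         n_reverse_rows = n_reverse_rows,
         n_only_site_rows = n_only_site_rows,
         outlier_patient = outlier_patient,
         seed = as.integer(seed)),
    class = "proteome_design"
  )
}

#' Generate a synthetic protein quantification table
#'
#' Draws a cohort (patients, spots per patient), renders the log2
#' abundance model, applies the MNAR missingness model, appends flagged
#' contaminant/reverse/site rows and returns a raw-scale
#' [protein_quant_table()] with ground truth attached
#' (see [ground_truth()]): per-protein designed class and log2 fold
#' change, and per-sample class/outlier status.
#'
#' @param design a [proteome_design()].
#' @return a raw-scale [protein_quant_table()], deterministic given the
#'   design (including its seed).
#' @export
generate_protein_table <- function(design) {
  if (!inherits(design, "proteome_design")) stopf("design must be a proteome_design")
  classes <- names(design$patients_per_class)

  # Cohort layout: patient ids, classes, spots per patient.
  cohort <- with_seed(derive_seed(design$seed, "cohort"), {
    pid <- 0
    rows <- list()
    for (cls in classes) {
      for (k in seq_len(design$patients_per_class[[cls]])) {
        pid <- pid + 1
        n_spots <- sample(seq(design$spots_per_patient_range[1],
                              design$spots_per_patient_range[2]), 1)
        rows[[pid]] <- data.frame(
          patient_id = sprintf("P%02d", pid), class = cls,
          spot_id = seq_len(n_spots), stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  })
  cohort$sample_id <- paste0(cohort$patient_id, "_s", cohort$spot_id)
  outlier_id <- NA_character_
  if (!is.null(design$outlier_patient)) {
    cls_patients <- unique(cohort$patient_id[cohort$class == design$outlier_patient$class])
    outlier_id <- cls_patients[length(cls_patients)]
  }

  n_prot <- design$n_proteins_total
  n_spec <- design$n_class_specific_per_class
  protein_class <- rep(NA_character_, n_prot)
  if (n_spec > 0) {
    protein_class[seq_len(3 * n_spec)] <- rep(classes[seq_len(3)], each = n_spec)
  }
  protein_ids <- sprintf("PROT%04d", seq_len(n_prot))

  n_samples <- nrow(cohort)
  patients <- unique(cohort$patient_id)
  vals <- matrix(NA_real_, n_prot, n_samples)
  a <- design$missingness_model[[1]]
  b <- design$missingness_model[[2]]

  for (p in seq_len(n_prot)) {
    row <- with_seed(derive_seed(design$seed, "protein", p), {
      mu <- stats::rnorm(1, design$base_log_intensity_mean,
                         design$base_log_intensity_sd)
      pat_dev <- stats::rnorm(length(patients), 0, design$patient_noise_sd)
      names(pat_dev) <- patients
      effect <- function(sample_class, patient) {
        if (is.na(protein_class[p])) return(0)
        if (!is.na(outlier_id) && patient == outlier_id) {
          w <- design$outlier_patient$weights
          return(design$class_effect_log2fc *
                   sum(w[names(w) == protein_class[p]]))
        }
        if (sample_class == protein_class[p]) design$class_effect_log2fc else 0
      }
      eff <- vapply(seq_len(n_samples), function(s) {
        effect(cohort$class[s], cohort$patient_id[s])
      }, numeric(1))
      log2x <- mu + eff + pat_dev[cohort$patient_id] +
        stats::rnorm(n_samples, 0, design$spot_noise_sd)
      p_miss <- stats::plogis(a + b * log2x)
      miss <- stats::runif(n_samples) < p_miss
      log2x[miss] <- NA
      log2x
    })
    vals[p, ] <- 2^row
  }

  # Flagged filler rows: plausible intensities, excluded by flag filtering.
  n_flag <- design$n_contaminant_rows + design$n_reverse_rows +
    design$n_only_site_rows
  if (n_flag > 0) {
    flag_vals <- with_seed(derive_seed(design$seed, "flagged"), {
      matrix(2^stats::rnorm(n_flag * n_samples,
                            design$base_log_intensity_mean,
                            design$base_log_intensity_sd),
             n_flag, n_samples)
    })
    flag_ids <- c(
      sprintf("CON__C%03d", seq_len(design$n_contaminant_rows)),
      sprintf("REV__R%03d", seq_len(design$n_reverse_rows)),
      sprintf("SITE__S%03d", seq_len(design$n_only_site_rows))
    )
    vals <- rbind(vals, flag_vals)
    protein_ids <- c(protein_ids, flag_ids)
  }
  flags <- data.frame(
    contaminant = c(rep(FALSE, n_prot),
                    rep(c(TRUE, FALSE, FALSE),
                        c(design$n_contaminant_rows, design$n_reverse_rows,
                          design$n_only_site_rows))),
    reverse = c(rep(FALSE, n_prot),
                rep(c(FALSE, TRUE, FALSE),
                    c(design$n_contaminant_rows, design$n_reverse_rows,
                      design$n_only_site_rows))),
    only_by_site = c(rep(FALSE, n_prot),
                     rep(c(FALSE, FALSE, TRUE),
                         c(design$n_contaminant_rows, design$n_reverse_rows,
                           design$n_only_site_rows)))
  )

  table <- protein_quant_table(
    protein_ids = protein_ids, intensities = vals,
    sample_meta = cohort[, c("sample_id", "patient_id", "class", "spot_id")],
    flags = flags, scale = "raw"
  )
  attr(table, "histomol_truth") <- list(
    protein_truth = data.frame(
      protein_id = protein_ids[seq_len(n_prot)],
      class_specific = protein_class,
      log2fc = ifelse(is.na(protein_class), 0, design$class_effect_log2fc),
      stringsAsFactors = FALSE
    ),
    sample_truth = data.frame(
      sample_id = cohort$sample_id, patient_id = cohort$patient_id,
      class = cohort$class,
      is_outlier = !is.na(outlier_id) & cohort$patient_id == outlier_id,
      stringsAsFactors = FALSE
    )
  )
  table
}
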