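#!/usr/bin/env Rscript
# Simulate the two synthetic cohorts all downstream analyses run on, and
# export one MSI section in the exchange formats (imzML + ground-truth
# mask TSV) plus the proteinGroups-style quantification table.
#
# MSI cohort: 23 patients (9 ccRCC, 9 RO, 5 ChRCC), one phantom section
# each, signature peaks at the discriminating m/z values (ccRCC: 723.5,
# 704.5; RO: 806.5, 1640.0; ChRCC: 1169.5, 1039.5).
# Proteomics cohort: 28 patients (12 ccRCC, 11 RO, 5 ChRCC), 2-6
# extraction spots each, 400 proteins (30 class-specific), MNAR
# missingness, and one sarcomatoid-like outlier patient mixing the
# ChRCC and ccRCC profiles.

library(histomol)

seed <- 1
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- run_config(seed = seed)

cat("Generating the 23-patient MSI phantom cohort...\n")
cohort <- generate_msi_cohort(n_per_class = cfg$msi_cohort,
                              seed = derive_seed(seed, "msi-cohort"))
classes <- table(vapply(cohort, function(d) d$metadata$condition, character(1)))
cat(sprintf("  %d sections (%s); %d pixels each\n",
            length(cohort),
            paste(sprintf("%s %d", names(classes), classes), collapse = ", "),
            n_pixels(cohort[[1]])))

# one example section on disk in exchange formats
example <- cohort[[1]]
write_imzml(example, file.path(out, "example_section"))
write_truth_mask(example, file.path(out, "example_section_mask.tsv"))
cat(sprintf("  wrote %s/example_section.{imzML,ibd} and its mask TSV\n", out))

cat("Generating the 28-patient protein quantification table...\n")
design <- proteome_design(seed = derive_seed(seed, "prot-cohort"))
tab <- generate_protein_table(design)
truth <- ground_truth(tab)
write_protein_table(tab, file.path(out, "protein_groups.tsv"))
cat(sprintf(
  "  %d protein rows (%d flagged) x %d extraction-spot samples, %.1f%% missing\n",
  nrow(tab$intensities), sum(tab$flags$contaminant | tab$flags$reverse |
                               tab$flags$only_by_site),
  ncol(tab$intensities), 100 * mean(is.na(tab$intensities))
))
cat(sprintf("  outlier patient: %s (ChRCC label, ChRCC/ccRCC mixture profile)\n",
            unique(truth$sample_truth$patient_id[truth$sample_truth$is_outlier])))
cat(sprintf("  wrote %s/protein_groups.tsv (+ metadata TSV)\n", out))
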