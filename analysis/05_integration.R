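#!/usr/bin/env Rscript
# Integration of the two modality calls: (1) the published 23-patient
# decision table is reproduced from its printed MSI and LC-MS/MS
# diagnosis columns; (2) the synthetic sarcomatoid-analog patient is
# pushed through both tracks and must land on "further validation".

library(histomol)

seed <- 1
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- run_config(seed = seed)

cat("Applying the decision table to the published per-patient columns...\n")
t1 <- integrate_table(load_integration_table())
utils::write.table(t1, file.path(out, "integration_table.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
n_ok <- sum(t1$derived_conclusion == t1$expected_conclusion)
cat(sprintf("  %d of %d conclusions reproduced\n", n_ok, nrow(t1)))
if (n_ok < nrow(t1)) {
  print(t1[t1$derived_conclusion != t1$expected_conclusion, ])
}

cat("Scoring the sarcomatoid-analog section against the cohort model...\n")
msi <- run_msi_track(cfg)
model <- fit_plsda(msi$features, msi$features$row_groups$condition,
                   cfg$n_components)
analog <- msi_outlier_phantom(seed = derive_seed(seed, "outlier"),
                              grid_width = 30, grid_height = 30)
truth <- ground_truth(analog)
mask <- truth[truth$label == analog$metadata$condition, c("x", "y")]
feats <- process_msi_section(analog, mask, cfg)$features
call <- patient_call(predict(model, feats$values),
                     classes = model$class_order, patient_id = "OUTLIER")
irr <- flag_irregular(call)
cat(sprintf("  MSI medians: %s\n",
            paste(sprintf("%s %.3f", names(call$median_scores),
                          call$median_scores), collapse = ", ")))
cat(sprintf("  winner %s, ambiguous with {%s}; irregular: %s (%s)\n",
            call$winner, paste(call$ambiguous_with, collapse = ", "),
            irr$irregular, irr$reason))

prot <- run_prot_track(cfg)
prot_call <- prot$calls[[prot$outlier_patient]]
cat(sprintf("  LC-MS/MS call for %s: %s, irregular: %s\n",
            prot$outlier_patient, prot_call$class, prot_call$irregular))

final <- integrate_calls(
  msi_call(call$winner, call$ambiguous_with, irregular = irr$irregular,
           patient_id = "OUTLIER"),
  prot_call
)
cat(sprintf("  integrated conclusion: %s (rule: %s)\n",
            final$conclusion, final$rule))
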