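#!/usr/bin/env Rscript
# Intra-tumor heterogeneity: a section whose tumor area holds two
# distinct histo-molecular sub-regions. Segmentation separates the two
# clusters; extraction spots are grouped by cluster (4 vs 2 spots) and
# the corresponding quantification samples are contrasted in a volcano
# comparison (Welch test, p <= 0.01 and >= 2-fold).

library(histomol)

seed <- 1
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- run_config(seed = seed)

cat("Simulating a section with two intra-tumor sub-regions...\n")
sigs <- default_signature_peaks()
sigs$tumor_core <- data.frame(mz = c(806.5, 1640.0),
                              mean_intensity = c(120, 100), cv = 0.25)
sigs$tumor_edge <- data.frame(mz = c(806.5, 1169.5, 1039.5),
                              mean_intensity = c(60, 80, 70), cv = 0.25)
spec <- msi_phantom_spec(
  grid_width = 16, grid_height = 16,
  regions = list(rect_region(3, 9, 3, 12, "tumor_core"),
                 rect_region(10, 13, 3, 12, "tumor_edge")),
  class_signature_peaks = sigs,
  seed = derive_seed(seed, "hetero")
)
ds <- generate_msi_phantom(spec, patient_id = "HET")

ds2 <- subtract_baseline_msi(ds, cfg$baseline_half_window)
peaks <- filter_peak_frequency(
  align_peaks(pick_peaks(ds2, cfg$peak_stride, cfg$snr_min),
              cfg$align_tolerance), 0.1)
fm <- resample_height(ds2, peaks, cfg$height_tolerance)
seg <- spatial_shrunken_centroids(
  fm, params = segmentation_params(k_init = cfg$seg_k_init, r = cfg$seg_r,
                                   s = cfg$seg_s,
                                   seed = derive_seed(seed, "hetero-seg"))
)
truth <- ground_truth(ds)
core_lab <- seg$labels[which(truth$label == "tumor_core")[1]]
edge_lab <- seg$labels[which(truth$label == "tumor_edge")[1]]
core_px <- data.frame(x = truth$x[seg$labels == core_lab],
                      y = truth$y[seg$labels == core_lab])
edge_px <- data.frame(x = truth$x[seg$labels == edge_lab],
                      y = truth$y[seg$labels == edge_lab])
cat(sprintf("Segmentation found %d clusters; tumor core %d px, edge %d px\n",
            nrow(seg$centroids), nrow(core_px), nrow(edge_px)))

# extraction spots: 4 in the core cluster, 2 in the edge cluster
spots <- data.frame(
  sample_id = letters[1:6],
  x = c(4, 6, 8, 5, 11, 12), y = c(5, 8, 10, 11, 6, 10)
)
groups <- compare_regions(core_px, edge_px, spots)
cat(sprintf("Spot grouping: cluster A (%s) vs cluster B (%s)\n",
            paste(groups$group_a, collapse = ","),
            paste(groups$group_b, collapse = ",")))

# matched quantification samples: 400 proteins, 40 truly shifted
# between the two regions by 1.5 log2 units
n_prot <- 400; n_shift <- 40
vals <- with_seed(derive_seed(seed, "hetero-prot"), {
  m <- matrix(stats::rnorm(n_prot * 6, 24, 0.4), n_prot)
  m[seq_len(n_shift), 5:6] <- m[seq_len(n_shift), 5:6] + 1.5
  m
})
tab <- protein_quant_table(
  sprintf("PROT%04d", seq_len(n_prot)), 2^vals,
  data.frame(sample_id = letters[1:6], patient_id = "HET",
             class = "RO", spot_id = 1:6)
)
res <- volcano_compare(log_transform(tab), groups$group_a, groups$group_b,
                       p_max = 0.01, min_fold = 2)
utils::write.table(res, file.path(out, "heterogeneity_volcano.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf(
  "Volcano (cluster B / cluster A, p <= 0.01, >= 2-fold): %d significant (%d up in B)\n",
  sum(res$significant), sum(res$direction == "up_in_b")))
cat(sprintf("True shifted proteins recovered: %d of %d\n",
            sum(res$significant[seq_len(n_shift)]), n_shift))
cat("Note: with only 2 extraction spots in the edge cluster the Welch\n")
cat("test has very few degrees of freedom; recovery is power-limited,\n")
cat("not threshold-limited.\n")
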