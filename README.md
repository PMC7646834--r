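# histomol

Dual-modality classification of renal tumor subtypes — clear cell renal
cell carcinoma (ccRCC), renal oncocytoma (RO) and chromophobe renal cell
carcinoma (ChRCC) — from formalin-fixed paraffin-embedded tissue
sections, for computational proteomics and imaging mass spectrometry
researchers. The package implements the full analysis workflow as tested,
reusable functions, plus a synthetic-data module that generates both
input modalities with known ground truth, so every stage is benchmarked
without access to patient data.

**MSI track** — MALDI mass spectrometry imaging (imzML in/out): baseline
subtraction, TIC normalization, peak picking in every 10th spectrum with
greedy alignment, "height" resampling, spatially-aware shrunken-centroid
segmentation (soft-thresholded statistic
`d_kj = (x̄_kj − x̄_j)/(m_k(s_j + s0))`, spatially smoothed reassignment),
tumor-pixel extraction, resampling to the common m/z 700–2500 grid at
0.25 Da (7201 features), and three-class PLS-DA (NIPALS PLS2 on one-hot
labels) under leave-one-patient-out cross-validation. A patient's call is
the class with the highest median pixel score; classes within 10% of the
winner's median are reported as indistinguishable (margin rule).

**Proteomics track** — label-free protein quantification tables
(MaxQuant proteinGroups dialect): flag filtering, log2 transform, ≥70%
valid-value filter, per-protein one-way ANOVA with Benjamini–Hochberg
FDR 0.01 (computed on unimputed values), down-shifted normal imputation
(`N(μ − 1.8σ, (0.3σ)²)` per column), Z-scoring, hierarchical clustering,
PCA with 95% prediction ellipses, Welch volcano contrasts, and one-vs-rest
SVM classification with k-fold CV, kernel comparison and ranked
feature-count optimization.

**Integration** — a total decision table merges the two per-patient
calls (irregular on either side → "further validation"; agreement or
resolvable ambiguity → the class; disagreement → proteomics class +
"further validation"), with an irregularity flag for anomalous patients
such as a sarcomatoid transformation co-scoring ccRCC and ChRCC.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
cohorts and write their tables under `results/`. `analysis/02_msi_track.R`
generates 23 phantom sections (9 ccRCC / 9 RO / 5 ChRCC) with the
class-discriminating peaks at m/z 723.5/704.5 (ccRCC), 806.5/1640.0 (RO)
and 1169.5/1039.5 (ChRCC), runs the full pipeline and prints:

```
Pixel-level accuracy: 100.0% overall (ccRCC 100%, RO 100%, ChRCC 100%)
Patient-level: 23 of 23 called correctly by the median rule
Top ccRCC features: m/z 704.50 (b=0.00178), m/z 723.50 (b=0.00152), ...
Top RO features: m/z 1640.00 (b=0.00214), m/z 806.50 (b=0.00172), ...
Top ChRCC features: m/z 1039.50 (b=0.00251), m/z 1169.50 (b=0.00231), ...
```

i.e. on clean phantoms every pixel and patient is recovered, and the
signed PLS coefficients rank exactly the planted signature masses as the
most class-discriminating features. `analysis/03_proteomics_track.R`
reports, for the 28-patient table (400 proteins, 30 class-specific):

```
Significant proteins at FDR 0.01: 50 of 333 tested
k = 5 rbf-kernel CV error: 0.0% over 96 extraction spots
Outlier patient P28 irregular by the ellipse rule: TRUE
  minimal feature count with zero error: 15 of 50
  error at 4 features: 4.2%
```

— zero cross-validated error at the full feature set, degrading as the
ranked feature count shrinks. `analysis/05_integration.R` reproduces all
23 conclusions of the published integration table from its printed
per-modality columns and routes the synthetic sarcomatoid analog (MSI
medians ccRCC 0.486 vs ChRCC 0.510, an irregular near-tie; proteomics
ellipse flag) to "further validation".

Minimal API example:

```r
library(histomol)
cohort <- generate_msi_cohort(c(ccRCC = 9, RO = 9, ChRCC = 5), seed = 1)
res <- run_msi_track(run_config(seed = 1), cohort = cohort)
res$patient_accuracy          # per-patient winner, ambiguity set, correctness
res$calls[["P01"]]            # median scores and margin-rule call
```

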