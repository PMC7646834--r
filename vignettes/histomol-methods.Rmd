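---
title: "Methods: dual-modality histo-molecular classification of renal tumor sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-modality histo-molecular classification of renal tumor sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem and the workflow

Renal tumor subtypes — clear cell renal cell carcinoma (ccRCC, malignant),
renal oncocytoma (RO, benign) and chromophobe renal cell carcinoma (ChRCC,
malignant) — overlap histologically, and the distinction matters: a ccRCC
misread as RO can cost a patient surgery they needed. `histomol` implements
a dual-modality classification workflow over formalin-fixed
paraffin-embedded (FFPE) tissue sections:

1. **MSI track.** MALDI mass spectrometry imaging acquires one peptide
   spectrum per 150 µm pixel. Spectra are preprocessed, each section is
   segmented by spatially-aware shrunken-centroid clustering, tumor-cluster
   pixels are extracted, and a three-class PLS-DA model classifies every
   tumor pixel under leave-one-patient-out cross-validation (LOPO-CV). A
   patient's call is the class with the highest median pixel score, with a
   10% margin rule marking near-ties as indistinguishable.
2. **Proteomics track.** In-situ tryptic digestion of 2–6 small tumor areas
   per section, 15-minute LC-MS/MS runs, and label-free quantification give
   a protein × extraction-spot table. After flag filtering, log2 transform,
   a 70% valid-value filter and one-way ANOVA with Benjamini–Hochberg FDR
   0.01, missing values are imputed from a down-shifted normal and a
   support vector machine classifies the spots under k-fold CV.
3. **Integration.** The two per-patient calls are merged by a decision
   table into a single conclusion, with an irregularity flag routing
   anomalous patients (e.g. a sarcomatoid transformation that resembles
   two classes at once) to further validation.

Because no patient data is deposited, a synthetic-data module generates
both input kinds with known ground truth; every downstream stage is
benchmarked against that truth.

# Synthetic data

## MSI phantoms

A phantom section (`msi_phantom_spec()` / `generate_msi_phantom()`) is a
grid of pixels partitioned into regions (tumor blob, stroma annulus,
background). Each pixel's spectrum is built generatively:

* Gaussian peaks (FWHM 0.5 Da) at the class signature m/z — ccRCC: 723.5
  and 704.5; RO: 806.5 and 1640.0; ChRCC: 1169.5 and 1039.5 — plus shared
  tissue peaks present in all tissue classes (e.g. 842.51, the tryptic
  autolysis product). Peak heights vary per pixel (CV 0.25).
* A per-pixel total-ion-current factor (log-normal, mean 1, CV 0.15),
  emulating matrix and ionization inhomogeneity.
* An exponentially decaying baseline `A exp(-λ(m − m_min))` with A = 2,
  λ = 0.002/Da, and i.i.d. Gaussian noise (SD 0.5); the sum is clipped at
  zero. The acquisition axis is m/z 600–3000 at 0.25 Da.

Each pixel draws from its own derived random stream, so subsetting a
region never changes the remaining pixels. The defaults (16 × 16 grid,
~60-pixel tumor blob) are chosen so a 23-patient cohort processes in
minutes on one CPU; the per-patient signature intensities are additionally
modulated by a log-normal patient effect (CV 0.1) to emulate
patient-to-patient tumor heterogeneity.

What the phantom does **not** emulate: mass-dependent resolution and
calibration drift, isotope envelopes, chemical noise structure, spatially
correlated matrix effects, and partial-volume mixtures at region borders.
Passing benchmarks on phantoms therefore demonstrates correctness of the
pipeline's statistics and bookkeeping, not instrument-level robustness.

## Protein quantification tables

`proteome_design()` / `generate_protein_table()` emulate a MaxQuant
proteinGroups export: on the log2 scale, protein p in sample s (patient q,
class c) is

    log2 x_ps = mu_p + effect_p(c) + patient_pq + spot_ps

with `mu_p ~ N(24, 2)` (log2 LFQ units), `effect_p(c)` = 2 log2 units for
the 10 proteins designed specific to each class (30 of 400), patient and
spot noise SDs 0.5 and 0.4. Missingness is missing-not-at-random:
`P(missing) = plogis(17 − 0.8 · log2 x)`, i.e. ~10% at the mean abundance
and rising steeply below it (~15% overall). Contaminant / reverse /
identified-by-site rows are appended and flagged. The cohort is 12 ccRCC,
11 RO and 5 ChRCC patients with 2–6 extraction spots each; the last ChRCC
patient is the sarcomatoid analog, its abundance profile a convex 0.5/0.5
mixture of the ChRCC and ccRCC profiles. The totals (400 proteins, 30
informative) are tunable, desk-scale stand-ins for the study's reported
magnitudes, not fixed truths.

# MSI processing choices

* **Baseline**: rolling minimum over a 2 × 50 Da window followed by a
  moving average of the same width, capped at the signal. For speed the
  baseline is evaluated on a decimated block-minimum grid and linearly
  interpolated; the result is still bounded by the signal, removes flat
  and slowly-decaying backgrounds exactly, and preserves isolated peak
  heights within 5%.
* **TIC normalization** scales every spectrum to the dataset-mean TIC
  (not 1.0), keeping intensities in instrument-like units; it is applied
  after tumor-pixel extraction so that off-tissue background noise is not
  amplified to tissue scale.
* **Peak picking** takes local maxima in every 10th spectrum with a
  signal-to-noise floor; noise is 1.4826 × the median absolute deviation
  of the spectrum. The function default floor is 3; the workflow uses 6
  because the MAD of a sparse baseline-subtracted spectrum underestimates
  the noise and the extreme noise maxima in a ~10,000-point spectrum reach
  ~4 MAD units. **Alignment** merges peaks greedily in ascending m/z into
  groups within 0.25 Da of the running intensity-weighted mean; a
  frequency filter then keeps peaks recurring in ≥ 10% of the sampled
  spectra — recurrence, not amplitude, is what separates real peaks from
  noise maxima.
* **Height resampling** takes the window maximum within ±0.125 Da (half
  the grid step) of each reference peak. **Grid resampling** restricts to
  m/z 700–2500 and interpolates linearly at 0.25 Da steps with inclusive
  endpoints — 7201 features, the common axis on which all patients are
  pooled for classification.

# Spatially-aware shrunken-centroid segmentation

Each iteration: per cluster k and feature j the mean `x̄_kj`, the pooled
within-cluster SD `s_j` with stabilizer `s0 = median(s_j)`, and the
statistic `d_kj = (x̄_kj − x̄_j) / (m_k (s_j + s0))` with
`m_k = sqrt(1/n_k − 1/n)`, soft-thresholded by the shrinkage parameter s;
the shrunken centroid is rebuilt from the thresholded statistic. Pixels
are reassigned to the cluster minimizing a spatially smoothed
standardized distance: a weighted average over the Chebyshev
radius-r neighborhood with Gaussian spatial weights
(σ = r/2), optionally multiplied by adaptive similarity weights
(`exp(−‖x_u − x_center‖²/(2σ̂²))`, σ̂² the mean neighbor distance);
weights are renormalized per pixel. Initialization is seeded k-means
(capped at the number of distinct rows); empty clusters are dropped, not
reseeded. Defaults for the phantom are r = 1, k_init = 4 (tumor, stroma,
background plus one spare), s = 0; raising s merges clusters monotonically
and s saturating the largest |d_kj| collapses everything to one cluster.
Tumor clusters are selected by overlap with the reference annotation
(Jaccard ≥ 0.5 default; a precision variant — fraction of cluster pixels
inside the annotation — is used in the workflow because one tumor may
split into several clusters, each fully inside the annotation).

# PLS-DA pixel classification

Labels are one-hot encoded, X and Y mean-centered, and components
extracted by NIPALS PLS2; predictions are continuous per-class scores. At
full rank the predictions coincide with ordinary least squares — the test
suite asserts this equivalence to 1e-6 as an oracle. Cross-validation is
strictly patient-grouped: all pixels of the held-out patient leave the
training set together. The per-fold coefficient path (`B_a` from the first
a components) makes the component sweep of `choose_n_components()` cost a
single fit per fold; the sweep is capped at 34 and ties resolve to the
smallest count. The cohort benchmark uses 5 components — on phantoms with
two discriminating features per class the accuracy plateaus by 3.

**Patient calls.** The median pixel score per class is the patient score;
the winner is the argmax, and any class within 10% of the winner's median
(relative to its absolute value) joins the ambiguity set. A non-positive
winner median is declared unclassifiable rather than ambiguous. Scores are
raw PLS predictions; they are not rescaled to [0, 1].

**A LOPO artifact worth knowing.** If two classes' spectral signatures are
made fully identical in the generator, held-out patients do *not* receive
near-tied scores: their pixels carry no discriminative signal, so their
predicted scores collapse to the training-fold class proportions, and
holding out one patient of class A leaves A under-represented — every
held-out A patient is then decisively mis-scored toward B with a relative
gap of about 1/n per class. Margin-rule ambiguity instead arises the way
it does in real tissue: a *section* whose spectrum carries both classes'
signatures. A 0.5/0.5 RO/ChRCC mixture section scored against the clean
cohort model receives medians within a few percent of each other and an
RO/ChRCC ambiguity set; the ChRCC/ccRCC mixture (the sarcomatoid analog)
receives the same near-tie on the pair the irregularity rule does not
exempt. The analog is rendered on a 30 × 30 section so the median gap's
Monte-Carlo noise (∝ 1/√pixels) is small relative to the 10% margin.

# Proteomics statistics

The pipeline order is fixed and guarded by the table's scale field and
explicit `NA` missingness: flag filter → log2 → valid-value filter (≥ 70%
of samples, inclusive) → one-way ANOVA on *unimputed* valid values with BH
FDR 0.01 → imputation only for PCA and classification. Testing before
imputation avoids significance inflated by imputed values; the ANOVA is
the classic equal-variance F test per protein, with proteins lacking two
valid values in two classes marked untestable rather than non-significant.
Note that spot-level ANOVA treats a patient's spots as independent — the
same pseudo-replication present in the emulated workflow — so the FDR
calibration test uses patient-free null data.

* **Imputation** draws each missing entry of a sample column from
  `N(μ_col − 1.8 σ_col, (0.3 σ_col)²)`, the down-shifted normal
  convention for left-censored label-free data; both constants are
  configurable, valid values are never altered, and draws are seeded.
* **Z-scoring** uses the population SD (N denominator): row (1, 2, 3)
  becomes (−1.2247, 0, 1.2247), and the transform is idempotent.
* **Hierarchical clustering** defaults to correlation distance with
  average linkage (the convention of the heatmap tooling this feeds);
  Euclidean and other linkages are available.
* **PCA prediction ellipses**: per group, the 95% region for a *new*
  observation, `(x − m)' S⁻¹ (x − m) ≤ 2(n−1)(n+1)/(n(n−2)) F(0.95; 2,
  n−2)` on the first two component scores; groups smaller than 3 get no
  ellipse. Monte-Carlo coverage of fresh draws is asserted at ±3 SE.
* **Volcano contrast** between two spot groups: Welch t-test on log2
  values, significant iff p ≤ 0.01 and |mean difference| ≥ 1 log2 unit;
  the sign is group B minus group A.

# SVM classification

Multiclass classification is one-vs-rest: one binary SVM per class, the
per-class score is the signed decision value (orientation resolved from
the decision-value column label, which follows training-data order), and
the highest score classifies the sample. Defaults: cost 10, RBF kernel
with γ = 1/(p · Var(training values)); feature standardization and the
ANOVA-F feature ranking are fitted inside each training fold only. Folds
are stratified by class at the sample level by default — the emulated
design — with patient-grouped folds available and recommended, because
2–6 near-replicate spots per patient leak across sample-level folds. The
leakage is real and measurable: under sample-level folds with permuted
labels the classifier performs *better* than chance (a twin spot in
training reveals the test spot's permuted label), so the chance-level
calibration permutes labels at the patient level under patient-grouped
folds. Feature-count optimization re-ranks per training fold and reports
the error over a feature-count grid plus the smallest count achieving
zero error; at the full feature set it reproduces the plain CV error
exactly (same fold seed).

# Integration

The decision table is total over (MSI call, LC-MS/MS call):

1. either side irregular → **further validation**;
2. LC-MS/MS class within the MSI winner-or-ambiguity set → the LC-MS/MS
   class (this resolves RO/ChRCC ambiguities);
3. otherwise → **LC-MS/MS class / further validation** — disagreements
   resolve toward the proteomics call, the track with the lower
   cross-validated error.

Irregularity: (a) an MSI near-tie (within the margin) between a class
pair *other than* {RO, ChRCC} — RO–ChRCC similarity is histologically
expected, ccRCC–ChRCC co-scoring is not; (b) a patient whose spots fall
outside the 95% prediction ellipse of their predicted class. Rule (b)
fits the ellipse *excluding the tested patient's own spots* (an aberrant
patient must not widen the region meant to catch it) and requires both
the majority of spots and the patient centroid outside. The package's
copy of the published 23-patient table reproduces its conclusion column
in full under this table; the sarcomatoid row's printed conclusion
carries a post-hoc pathology annotation after an arrow, which the loader
strips before comparison.

# Problem sizes, seeds and degenerate inputs

The shipped benchmarks use 16 × 16 phantom sections (23 patients,
~1,400 tumor pixels pooled on 7,201 features), a 413 × 101 protein table,
200 null simulations for the FDR calibration and 10⁴ draws for the
imputation and ellipse checks — sizes chosen so the full suite runs in
minutes on a single core while keeping Monte-Carlo standard errors well
below the asserted tolerances. Every stochastic stage derives its seed
from one master seed (`derive_seed()`), and generators split streams per
pixel/protein so subsetting is stable. Degenerate inputs error early and
name the offender: all-zero spectra in TIC normalization, constant rows
in Z-scoring, columns with fewer than 3 valid values in imputation,
single-class inputs to any classifier or test, folds that lose a class,
empty masks and empty groups.

# Known limitations

* The spectra simulator is phenomenological; no peptide identities,
  isotopes or mass-calibration drift. Claims about instrument-level
  robustness cannot be made from these benchmarks.
* Spot-level CV (the default, for fidelity to the emulated design) is
  optimistic in the presence of patient effects; patient-grouped folds
  are one flag away and are what the permutation calibration uses.
* The spatial segmentation implements the shrunken-centroid update rules
  directly; its spatial weighting constants (Gaussian σ = r/2, adaptive
  bandwidth = mean neighbor distance) are declared package constants.
* Perseus' exact SVM scoring and feature-ranking internals are not
  public; one-vs-rest decision values and ANOVA-F ranking are the
  declared stand-ins.
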