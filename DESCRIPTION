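Package: histomol
Title: Histo-Molecular Classification of Renal Tumor Sections by MSI and
    Rapid Microproteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Dual-modality workflow for classifying renal tumor subtypes
    (clear cell renal cell carcinoma, renal oncocytoma, chromophobe renal
    cell carcinoma) from formalin-fixed paraffin-embedded tissue sections.
    One track processes MALDI mass spectrometry imaging data (imzML input,
    baseline subtraction, TIC normalization, peak picking and alignment,
    spatially-aware shrunken-centroid segmentation, PLS-DA pixel
    classification with leave-one-patient-out cross-validation and a
    10-percent margin rule for patient calls). The other applies
    label-free proteomics table statistics (flag filtering, valid-value
    filtering, ANOVA with Benjamini-Hochberg FDR, down-shifted normal
    imputation, hierarchical clustering, PCA with 95 percent prediction
    ellipses) and SVM classification with k-fold cross-validation and
    feature-count optimization. Patient-level calls from both tracks are
    integrated into a single diagnosis with an irregularity flag. A
    synthetic-data module generates MSI phantoms and protein quantification
    tables with known ground truth so the full pipeline is testable without
    patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
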