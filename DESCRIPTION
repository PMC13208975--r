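Package: pabcd
Title: Radiomic CT Volumetry and Opacification Staging for Chronic Rhinosinusitis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies paranasal sinus opacification on Hounsfield-unit
    calibrated CT. Classifies voxels inside a sinonasal volume of interest
    into air, soft tissue and bone by HU thresholds, extracts volumetric and
    densitometric parameters, and computes the P(ABCD) patency score
    (V_soft/(V_soft+V_air)) with its six-grade staging, ostiomeatal-complex
    patency scores, and the classical Lund-Mackay and modified (Zinreich)
    Lund-Mackay scores. Includes a seeded synthetic sinus phantom generator
    with exact ground truth, landmark-based VOI construction, and
    paired-cohort statistics (Wilcoxon signed-rank, Friedman, Bonferroni
    correction, Bland-Altman agreement) for before/after treatment designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
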