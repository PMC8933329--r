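Package: vrconn
Title: Visualized-Ratio Thresholded Structural Connectomes for Language
    Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds binarized structural brain networks from deterministic
    tractography thresholded by the per-fiber visualized ratio (VR), the
    fiber's maximal surviving fractional-anisotropy threshold expressed as
    a percentage of the subject-level maximum.  Provides readers and
    writers for TCK/TRK streamlines and NIfTI volumes, a synthetic
    phantom-cohort generator, construction of whole-brain, hemispheric and
    stimulation-mapping (nTMS positive/negative) region networks, graph
    metrics (average degree, global and local efficiency) at paired VR
    thresholds with their differences, and the group statistics layer
    (ANCOVA with a tumor-size covariate, t, chi-square, Mann-Whitney,
    rank correlation, Benjamini-Hochberg FDR) used to compare aphasic and
    non-aphasic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
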