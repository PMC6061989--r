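Package: panelDE
Title: Differential Evolution Selection of miRNA Biomarker Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Wrapper feature selection for two-class miRNA expression data.
    A differential evolution search over candidate miRNA index panels is
    driven by the 10-fold cross-validated accuracy of an RBF-kernel support
    vector machine evaluated on a component-analysis-enhanced view of the
    selected columns (PCA or kernel PCA, chosen empirically per dataset).
    Independent runs are aggregated by majority voting and the final panel
    is sized by a prefix-accuracy scan. Includes the closed-form
    random-selection null model for the expected number of distinct miRNAs
    reported across runs, an aggregated evaluation score combining accuracy,
    F-measure, Matthews correlation and AUC, cosine-similarity cluster
    homogeneity and separation diagnostics, and a synthetic two-class
    count-data generator with planted mean-shift, correlated and non-linear
    (xor) discriminative panels.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    kernlab,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
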