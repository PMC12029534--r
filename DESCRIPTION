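Package: metnam
Title: Stage-Wise Metabolic Network Analysis for Paired Tumor Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for LC-MS peak-table metabolomics of paired
    tumor and adjacent tissue cohorts. Provides internal-standard and
    tissue-weight normalization with pooled-QC RSD evaluation, paired
    Wilcoxon differential screening with Benjamini-Hochberg FDR control,
    PLS-DA with cross-validated component selection and permutation
    validation, set-based hypergeometric pathway over-representation,
    Fisher-z differential Spearman correlation networks, acylcarnitine
    ratio panels acting as beta-oxidation enzyme-activity proxies,
    discovery/validation biomarker ROC analysis, and a stage-wise
    network-topology method that extracts correlation subnetworks whose
    edge weights change monotonically across ordered tumor stages,
    together with a synthetic cohort generator that plants known effects
    and correlation trajectories for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    mixOmics,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
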