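Package: methdrift
Title: DNA Methylation Drift Analysis for Hematopoietic Cell Transplant Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying whole-blood DNA methylation drift between
    donors and recipients of hematopoietic cell transplants. Implements the
    multi-CpG Euclidean drift statistic (delta-Met) over pyrosequencing
    amplicon panels, donor/recipient pairwise comparisons and longitudinal
    trajectories, a mixture-based chimerism-fraction estimator, the bead-array
    altered-probe caller (detection-p filtering and strict delta-beta
    thresholding with gene collapsing), exact Wilcoxon and ROC/AUC outcome
    association, and a synthetic donor/recipient cohort generator with
    cell-type methylation signatures, blood-composition mixtures, chimerism
    mixing and assay noise, so every stage of the pipeline is testable
    without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
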