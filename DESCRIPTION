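Package: methyldecon
Title: Reference-Based Methylation Deconvolution and a Continuous B-Cell
    Differentiation Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for reference-based DNA methylation cell-type deconvolution
    by non-negative constrained projection, and for deriving a continuous
    two-reference differentiation index (B-Index) from purified tumor
    methylomes. Includes a diagnostic separating physical cell mixtures from
    single populations in per-CpG intermediate states, an epigenome-wide
    association engine on M-values with empirical-Bayes variance moderation
    and M-to-beta effect conversion, TOST equivalence screening against
    reference cell types, plain and stratified (Cochran-Mantel-Haenszel)
    feature enrichment tests, ROC/AUC classification metrics, and a fully
    seeded synthetic-data generator emulating the statistical structure each
    method assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), withr, pracma, limma, pROC, jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
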