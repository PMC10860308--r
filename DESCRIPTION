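Package: clutchvar
Title: Heterogeneity of Maternal mRNA Provisioning Across Single Eggs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies between-egg variability of maternally deposited
    transcripts from single-egg RNA-seq count matrices. Implements the
    filtering and TPM normalization steps used for single-egg libraries,
    per-clutch squared coefficients of variation (CV2), log10 CV2 ratio
    comparisons between clutches from heat-stressed and control mothers,
    five-fold variance-outlier calling with cross-generation overlaps,
    per-gene and global Bartlett variance-homogeneity tests with Bonferroni
    control, an ANCOVA-style trend test of the stress effect on CV2, and
    Fisher's exact tests on developmental outcomes. Ships a Gamma-Poisson
    single-egg count simulator with known variance-inflation ground truth
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
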