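Package: longenrich
Title: Semi-Supervised Longitudinal Enrichment of Imaging-Genetic Data
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns a participant-specific projection that compresses a
    variable-length history of multi-modal neuroimaging visits into a
    fixed-length "enriched" biomarker vector, jointly with a group-sparse
    factorization of static SNP genotypes and partially observed clinical
    scores.  The non-smooth robust objective (row-wise L2,1 losses, trace-norm
    coupling of all projections, group-structured sparsity on genetic
    loadings, L1-sparse regression weights) is minimized by iterative
    reweighting with an inner ADMM whose block updates are closed forms,
    linear systems and a Sylvester equation.  Includes a synthetic cohort
    generator with missing last visits and outlier injection, biomarker
    importance rankings from the fitted projections, and a downstream
    prediction harness (ridge and kernel regression with cross-validated
    hyperparameter search).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
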