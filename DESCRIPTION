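Package: neosplice
Title: Splice-Junction-Derived Immunotherapy Target Discovery on Synthetic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for nominating immunotherapy targets
    from alternative splicing. Implements Bayesian percent-spliced-in (PSI)
    quantification of local splice variations with binned Dirichlet posteriors,
    differential splicing (dPSI) by posterior convolution, tumor-specific
    neojunction calling, projection of junctions onto cell-surface protein
    topological domains for CAR-target nomination, junction-spanning peptide
    derivation with decoy-estimated FDR confirmation, single-cell junction
    screening for neoplastic-cell specificity, HLA class-I neoantigen filtering
    through a pluggable binding predictor, and RNA-binding-protein motif
    scanning. Ships a synthetic-cohort generator with planted ground truth so
    the whole cascade is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Matrix,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
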