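Package: remodelprint
Title: Comparative Exome Analysis of Remodelled and Non-Remodelled Airway Epithelia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the differential whole-exome comparison of
    paired non-remodelled (N) and remodelled (R) bronchial epithelial samples
    across non-COPD and COPD patients. Implements global and comparative
    variant-set and copy-number-alteration (CNA) set analyses, remodelled-only
    and group-exclusive recurrence filters for genes of interest, exact-coordinate
    CNA locus identity, Venn partitioning and unique fractions, hypergeometric
    gene-set enrichment with a log10 observed/expected strength statistic,
    Benjamini-Hochberg FDR correction, and cross-referencing of genes of
    interest against a whole-lung expression matrix. Ships a synthetic-cohort
    generator that plants known alterations with truth tables so every stage is
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
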