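Package: amdprio
Title: Regulatory Prioritization of Noncoding GWAS Risk Variants in RPE and Choroid
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for prioritizing noncoding GWAS risk
    variants using single-cell chromatin accessibility and enhancer-connectome
    evidence, developed around age-related macular degeneration (AMD) risk
    loci in the retinal pigment epithelium (RPE) and choroid. Provides linkage
    disequilibrium expansion of index variants, consequence and AlphaMissense
    classification, variant-peak intersection and enrichment, four
    enhancer-gene linking strategies (promoter co-accessibility, peak-gene
    correlation, HiChIP loop overlap, and Activity-by-Contact scoring),
    allele-specific STARR-seq analysis with moderated tests and empirical
    control-percentile thresholds, a Poisson/Fisher statistic for predicted
    allelic accessibility effects, and an at-least-3-of-8 criteria integration
    rule. A synthetic-data module generates every input with recorded ground
    truth so the full pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
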