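Package: mitomodqtl
Title: Mitochondrial RNA Modification Quantification and Nuclear QTL Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies m1A/m1G RNA modification levels at functionally
    important positions of the human mitochondrial transcriptome from
    RNA-seq pileup mismatch proportions, and maps them to nuclear genetic
    variants. Implements the full analysis chain: pileup-text parsing with
    base-quality filtering, per-site mismatch-rate phenotypes with coverage,
    site-mean and outlier masking rules, genotype and sample quality
    control with an exact Hardy-Weinberg test, covariate-adjusted linear
    methylation-QTL scans with genetic principal components and hidden
    expression factors, inverse-variance fixed-effects meta-analysis,
    additive two-locus tests, bootstrap causal mediation through cis-gene
    expression, upstream-gene expression consequences, linkage
    disequilibrium (D', r-squared) by phased counting or EM, and overlap
    with a GWAS catalogue. A synthetic-data generator with known ground
    truth emulates the multi-dataset, multi-tissue cohort structure for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
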