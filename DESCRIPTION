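Package: adaptscan
Title: Candidate-Gene Genotype-Environment and Genotype-Phenotype
    Association Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for detecting candidate adaptive loci in
    structured plant populations sampled across environmental gradients.
    Covers environmental principal component and canonical correlation
    analysis, VCF genotype filtering (depth, minor allele frequency,
    missingness, SNP density, linkage-disequilibrium pruning), gene-model
    SNP annotation, ancestry estimation by constrained matrix
    factorization with cross-entropy model choice, latent-factor
    association scans with genomic-inflation calibration and
    Benjamini-Hochberg control, redundancy-analysis outlier detection
    with permutation tests, partial-ordination variance partitioning,
    and additive polygenic scores.  A synthetic-data generator with
    planted environmental clines makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    vegan,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
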