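Package: permqtl
Title: Joint Methylation and Expression QTL Mapping with maxT Permutation
    Significance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for mapping quantitative trait loci (QTL)
    for CpG methylation (methQTL) and mRNA expression (eQTL) across multiple
    tissues from allele-dosage genotypes. Implements genotype and trait quality
    control (call-rate, Hardy-Weinberg exact test, minor-homozygote and
    imputation-quality filters, genotypic and methylation-based sex checks),
    rank-invariant normalization, covariate residualization, per-trait
    genome-wide dosage regression with maxT label-swapping permutation
    empirical p-values, false discovery rate thresholding with linkage
    disequilibrium rescue, cis/trans annotation, CpG-island calling,
    cis-enrichment distance scans, cross-tissue effect comparison,
    SNP-CpG-mRNA triplet analysis, and a seeded synthetic-data generator with
    planted effects for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    Matrix,
    jsonlite,
    yaml,
    ape,
    Biostrings,
    IRanges,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
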