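Package: meqtltools
Title: Cis-meQTL and cis-eQTL Mapping with Enrichment Analyses for Brain Tissue Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for mapping cis-acting methylation and
    expression quantitative trait loci (meQTLs/eQTLs) in modestly sized
    tissue cohorts. Provides Illumina 450K/HT-12-style probe and SNP
    quality control, subset quantile normalization, a covariate-adjusted
    additive linear-model cis scan with Benjamini-Hochberg FDR and
    per-covariate variance decomposition, methylation-expression
    correlation on confounder residuals, beta-value-matched Fisher
    enrichment of QTL-CpGs in genomic annotation tracks, LD clumping with
    MAF-matched empirical enrichment of QTL-SNPs against external SNP
    sets, and CADD/TFBS-based prioritization of QTL-SNPs. A synthetic
    cohort generator with block-LD genotypes, bimodal methylation
    beta-values and planted cis effects makes every stage testable
    without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
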