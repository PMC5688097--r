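#!/usr/bin/env Rscript
# Simulate the study cohort: 110 samples, block-LD genotype dosages
# (MAF > 5%), bimodal CpG beta-values with planted cis-meQTLs spanning
# variance fractions 0.10-0.85, log2 expression with planted cis-eQTLs
# (a few sharing their driver SNP with a meQTL), and covariates
# (gender, age, neuronal proportion). Outputs land in results/run/.

library(meqtltools)

cfg <- validate_config(list(seed = 20260921))
cfg$stages <- "simulate"
res <- run_pipeline(cfg, "results/run")

geno <- read_genotypes("results/run/genotypes_dosage.tsv")
truth <- read.delim("results/run/truth_meqtl.tsv", comment.char = "#")
cat(sprintf("cohort: %d samples x %d SNPs; %d planted meQTLs (R2 %.2f-%.2f)\n",
            length(geno$samples), nrow(geno$snps), nrow(truth),
            min(truth$variance_explained), max(truth$variance_explained)))
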