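#!/usr/bin/env Rscript
# LD-overlap enrichment of meQTL-SNPs against a GWAS hit list with
# planted overlap: clump both sets to quasi-independent index SNPs
# (r2 < 0.25 within 250 kb, keeping the most significant SNP), count LD
# overlaps, and compare against MAF-matched control sets drawn from the
# clumped non-QTL pool.

library(meqtltools)

cfg <- validate_config(list(seed = 20260921))
cfg$stages <- "enrich_ld"
run_pipeline(cfg, "results/run")

enr <- read.delim("results/run/ld_overlap_enrichment.tsv", comment.char = "#")
cat(sprintf("clumped targets: %d; observed overlap: %d; null %.2f +/- %.2f\n",
            enr$n_target_clumped, enr$observed_overlap, enr$null_mean,
            enr$null_sd))
cat(sprintf("enrichment %.2f-fold, empirical p %s (n_sets = %d)\n",
            enr$enrichment,
            ifelse(enr$empirical_p == 0, sprintf("< %.2g", 1 / enr$n_sets),
                   format(enr$empirical_p)), enr$n_sets))
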