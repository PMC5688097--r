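#!/usr/bin/env Rscript
# Methylation-expression correlation on confounder residuals (window
# anchored on the expression probe), and shared-driver detection: for
# correlated CpG-transcript pairs that are both QTLs, LD between the two
# top SNPs at r2 >= 0.4 flags a common genetic driver.

library(meqtltools)

cfg <- validate_config(list(seed = 20260921))
cfg$stages <- c("scan_meqtl", "scan_eqtl", "correlate")
run_pipeline(cfg, "results/run")

corr <- read.delim("results/run/correlations.tsv", comment.char = "#")
sig <- corr[corr$fdr_significant, ]
cat(sprintf("correlations: %d significant of %d tested; %.0f%% negative\n",
            nrow(sig), nrow(corr), 100 * mean(sig$direction < 0)))
drv <- read.delim("results/run/shared_drivers.tsv", comment.char = "#")
cat(sprintf("shared genetic drivers (r2 >= 0.4): %d pairs\n", nrow(drv)))
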