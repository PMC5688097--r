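#!/usr/bin/env Rscript
# Cis-meQTL and cis-eQTL scans: additive linear model per SNP-probe pair
# within +/-500 kb, adjusted for gender, age, neuronal proportion,
# 3 genotype PCs and hidden-confounder PCs (3 for methylation, 2 for
# expression); Benjamini-Hochberg FDR at 1% jointly over all cis pairs,
# and per-covariate variance decomposition for significant records.

library(meqtltools)

cfg <- validate_config(list(seed = 20260921))
cfg$stages <- c("scan_meqtl", "scan_eqtl")
run_pipeline(cfg, "results/run")

for (w in c("meqtl", "eqtl")) {
  s <- yaml::read_yaml(file.path("results/run", paste0(w, "_summary.yaml")))
  cat(sprintf("%s: %d/%d significant pairs at %d probes (p <= %.3g); ",
              w, s$n_significant_pairs, s$n_pairs_tested,
              s$n_significant_probes, s$p_threshold))
  cat(sprintf("top-pair median |beta| %.3g, median distance %.1f kb\n",
              s$median_abs_beta_top, s$median_distance_top / 1000))
}

# how much of the phenotype variance the genotype explains, per QTL probe
rec <- read_qtl_table("results/run/meqtl_records.tsv")
top <- rec[rec$fdr_significant, ]
top <- top[order(top$probe_id, top$p), ]
top <- top[!duplicated(top$probe_id), ]
cat(sprintf("meQTL genotype variance share: median %.1f%% (range %.1f-%.1f%%)\n",
            100 * median(top$r2_genotype), 100 * min(top$r2_genotype),
            100 * max(top$r2_genotype)))
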