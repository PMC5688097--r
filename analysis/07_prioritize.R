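#!/usr/bin/env Rscript
# Epigenomic prioritization of meQTL-SNPs: CADD-Phred thresholding
# (score > 5) with best-SNP-per-CpG selection, CpG creation/abolition
# calls from the sequence context, TFBS-alteration joins and CTCF
# over-representation, and GWAS-catalog matching. External scores are
# consumed as plain tables; here they are simulated with a planted CTCF
# excess among the best SNPs.

library(meqtltools)

rec <- read_qtl_table("results/run/meqtl_records.tsv")
geno <- read_genotypes("results/run/qc_genotypes.tsv")
rec$snp_pos <- geno$snps$pos[match(rec$snp_id, geno$snps$snp_id)]
sig <- rec[rec$fdr_significant, ]

set.seed(20260921)
snp_ids <- unique(rec$snp_id)
cadd <- data.frame(snp_id = snp_ids,
                   cadd_phred = rgamma(length(snp_ids), shape = 2, scale = 4))

pri <- filter_by_cadd(sig, cadd, threshold = 5)
best <- pri[pri$is_best_for_probe, ]
cat(sprintf("CADD > 5: %d records at %d CpGs; best-SNP mean CADD %.2f\n",
            nrow(pri), length(unique(pri$probe_id)), mean(best$cadd_phred)))

# CpG creation/abolition for the best SNPs, from simulated contexts
bases <- c("A", "C", "G", "T")
ctx <- paste0(sample(bases, nrow(best), TRUE), "C",
              sample(bases, nrow(best), TRUE))
eff <- vapply(seq_len(nrow(best)), function(i) {
  cpg_disruption(ctx[i], "C", "T")
}, character(1))
cat("CpG disruption calls among best SNPs:\n")
print(table(eff))

# TFBS joins with a planted CTCF excess in the best set
tfbs <- rbind(
  data.frame(snp_id = sample(best$snp_id, ceiling(nrow(best) * 0.4)),
             factor = "CTCF", delta_affinity = rnorm(ceiling(nrow(best) * 0.4))),
  data.frame(snp_id = sample(setdiff(snp_ids, best$snp_id), 30),
             factor = sample(c("CTCF", "REST", "SP1"), 30, TRUE,
                             prob = c(0.15, 0.5, 0.35)),
             delta_affinity = rnorm(30)))
best_j <- join_tfbs(best, tfbs)
bg <- pri[!pri$is_best_for_probe, ]
if (!nrow(bg)) bg <- data.frame(snp_id = setdiff(snp_ids, best$snp_id))
bg_j <- join_tfbs(bg, tfbs)
ctcf <- tf_overrepresentation(best_j, bg_j, "CTCF")
cat(sprintf("CTCF over-representation: OR %.2f (p = %.3g)\n",
            ctcf$odds_ratio, ctcf$p_value))

# GWAS-catalog matching at genome-wide significance
catalog <- data.frame(snp_id = sample(snp_ids, 40),
                      trait = sample(c("scz", "bd", "mdd"), 40, TRUE),
                      p = 10^-runif(40, 4, 12))
hits <- match_gwas_catalog(best, catalog, p_max = 5e-8)
cat(sprintf("catalog matches at p < 5e-8: %d\n", nrow(hits)))

dir.create("results", showWarnings = FALSE)
write_qtl_table(pri, "results/run/prioritized_meqtl.tsv")
cat("wrote results/run/prioritized_meqtl.tsv\n")
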