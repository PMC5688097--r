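#!/usr/bin/env Rscript
# SNP and CpG-probe quality control over the simulated cohort: call
# rate / MAF / exact-HWE filters for SNPs, and the CpG cascade
# (here only the "no SNP within the cis window" rule binds, since the
# synthetic arrays carry no detection-p or bead-count companions).

library(meqtltools)

cfg <- validate_config(list(seed = 20260921))
cfg$stages <- "qc"
run_pipeline(cfg, "results/run")

for (f in c("qc_snp_report.tsv", "qc_cpg_report.tsv")) {
  rep <- read.delim(file.path("results/run", f), comment.char = "#")
  cat(f, ":\n"); print(rep)
}
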