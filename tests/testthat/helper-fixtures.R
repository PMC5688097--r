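# Shared fixtures, built in code.

# genotype matrix from a literal samples x snps dosage matrix; positions
# default to a 10 kb grid on one chromosome
toy_genotypes <- function(dosage, pos = NULL, chrom = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(pos)) pos <- 10000L * seq_len(m)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  genotype_matrix(sprintf("S%03d", seq_len(nrow(dosage))),
                  data.frame(snp_id = sprintf("snp%03d", seq_len(m)),
                             chrom = chrom, pos = pos,
                             ref_allele = "A", alt_allele = "G",
                             stringsAsFactors = FALSE),
                  dosage)
}

toy_probe_matrix <- function(values, anchor_pos = NULL, chrom = NULL,
                             value_kind = "beta", prefix = "p") {
  values <- as.matrix(values)
  m <- ncol(values)
  if (is.null(anchor_pos)) anchor_pos <- 10000L * seq_len(m) + 500L
  if (is.null(chrom)) chrom <- rep("chr1", m)
  probe_matrix(sprintf("S%03d", seq_len(nrow(values))),
               data.frame(probe_id = sprintf("%s%03d", prefix, seq_len(m)),
                          chrom = chrom, anchor_pos = anchor_pos,
                          stringsAsFactors = FALSE),
               values, value_kind)
}

# dosage vectors with a prescribed LD structure: columns are copies of a
# base vector with k entries rotated, giving graded r2
rotated_copy <- function(x, k) c(utils::tail(x, k), utils::head(x, length(x) - k))

# small planted cohort used across engine tests
planted_cohort <- function(n = 110, seed = 7, v = c(0.3, 0.6)) {
  cfg <- sim_config(n_samples = n, n_snps = 60, ld_block_size = 10,
                    n_cpg_probes = 30, n_expr_probes = 20,
                    planted_meqtls = data.frame(snp = c(5, 25),
                                                probe = c(3, 11),
                                                variance_explained = v),
                    planted_eqtls = data.frame(snp = c(5, 45),
                                               probe = c(2, 9),
                                               variance_explained = c(0.5, 0.4)),
                    seed = seed)
  simulate_cohort(cfg)
}
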