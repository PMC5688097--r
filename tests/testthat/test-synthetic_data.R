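test_that("genotype simulation is a pure function of (config, seed)", {
  cfg <- sim_config(n_samples = 50, n_snps = 40, seed = 3)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosage, g2$dosage)
  g3 <- simulate_genotypes(cfg, seed = 4)
  expect_false(identical(g1$dosage, g3$dosage))
  # caller RNG state untouched
  set.seed(11); before <- .Random.seed
  invisible(simulate_genotypes(cfg))
  expect_identical(before, .Random.seed)
})

test_that("within-block LD hits the requested r2 target", {
  cfg0 <- sim_config(n_samples = 2000, n_snps = 50,
                     within_block_r2_target = 0, seed = 2)
  d0 <- simulate_genotypes(cfg0)$dosage
  r2_within <- function(d, bs = 10) {
    vals <- c()
    for (b in seq_len(ncol(d) / bs)) {
      r <- cor(d[, ((b - 1) * bs + 1):(b * bs)])^2
      vals <- c(vals, r[upper.tri(r)])
    }
    vals
  }
  expect_lt(mean(r2_within(d0)), 0.02)

  cfg8 <- sim_config(n_samples = 2000, n_snps = 50,
                     within_block_r2_target = 0.8, seed = 2)
  d8 <- simulate_genotypes(cfg8)$dosage
  adj <- sapply(seq_len(5), function(b) {
    cols <- ((b - 1) * 10 + 1):(b * 10)
    mean(diag(cor(d8[, cols[-10]], d8[, cols[-1]])^2))
  })
  expect_gt(mean(adj), 0.7)
  expect_lt(mean(adj), 0.9)

  # across blocks: independent
  across <- cor(d8[, 1:10], d8[, 11:20])^2
  expect_lt(mean(across), 0.02)

  expect_error(sim_config(within_block_r2_target = 0.99), "0.98")
})

test_that("empirical MAF respects the configured floor", {
  cfg <- sim_config(n_samples = 110, n_snps = 100, seed = 9)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$snps$maf >= 0.05))
  expect_true(all(g$snps$maf <= 0.5))
  expect_equal(g$snps$pos, 2000L * seq_len(100))
})

test_that("background methylation is bimodal and bounded", {
  cfg <- sim_config(n_samples = 110, n_snps = 40, n_cpg_probes = 400, seed = 5)
  g <- simulate_genotypes(cfg)
  m <- simulate_methylation(g, cfg)
  expect_true(all(m$values >= 0 & m$values <= 1))
  med <- apply(m$values, 2, median)
  # modes near 0 and 1: both tails hold roughly the mixture mass
  expect_gt(mean(med < 0.25), 0.30)
  expect_gt(mean(med > 0.75), 0.30)
  expect_lt(mean(med > 0.25 & med < 0.75), 0.30)
})

test_that("planted methylation effects realize the requested beta-scale R2", {
  cfg <- sim_config(n_samples = 2000, n_snps = 40, n_cpg_probes = 10,
                    planted_meqtls = data.frame(snp = c(1, 21),
                                                probe = c(1, 2),
                                                variance_explained = c(0.5, 0.25)),
                    seed = 13)
  g <- simulate_genotypes(cfg)
  m <- simulate_methylation(g, cfg)
  r2_1 <- cor(m$values[, 1], g$dosage[, 1])^2
  r2_2 <- cor(m$values[, 2], g$dosage[, 21])^2
  expect_gt(r2_1, 0.42); expect_lt(r2_1, 0.58)
  expect_gt(r2_2, 0.18); expect_lt(r2_2, 0.32)
  truth <- attr(m, "planted")
  expect_equal(truth$snp_id, c("snp00001", "snp00021"))
})

test_that("planted expression effects recover by OLS and nulls stay flat", {
  cfg <- sim_config(n_samples = 2000, n_snps = 40, n_expr_probes = 10,
                    planted_eqtls = data.frame(snp = 11, probe = 3,
                                               variance_explained = 0.25),
                    seed = 21)
  g <- simulate_genotypes(cfg)
  e <- simulate_expression(g, cfg)
  r2 <- cor(e$values[, 3], g$dosage[, 11])^2
  expect_gt(r2, 0.21); expect_lt(r2, 0.29)

  # null: no spuriously strong association among 100 probes x 100 SNPs
  cfg0 <- sim_config(n_samples = 110, n_snps = 100, n_expr_probes = 100,
                     seed = 22)
  g0 <- simulate_genotypes(cfg0)
  e0 <- simulate_expression(g0, cfg0)
  r <- cor(g0$dosage, e0$values)
  t <- r * sqrt(108 / (1 - r^2))
  p <- 2 * pt(-abs(t), df = 108)
  expect_gte(min(p), 1e-6)
})

test_that("simulated tracks carry the planted coverage odds", {
  ann <- data.frame(probe_id = sprintf("c%05d", 1:5000), chrom = "chr1",
                    anchor_pos = seq(1000, by = 1000, length.out = 5000))
  flags <- rep(c(TRUE, FALSE), c(1000, 4000))
  or_of <- function(odds, seed) {
    tr <- simulate_tracks(ann, flags, odds, seed = seed)
    inside <- overlap_flags(data.frame(chrom = ann$chrom, pos = ann$anchor_pos), tr)
    fisher_enrichment(sum(inside & flags), sum(!inside & flags),
                      sum(inside & !flags), sum(!inside & !flags))$odds_ratio
  }
  or_null <- or_of(1, 31)
  expect_gt(or_null, 0.8); expect_lt(or_null, 1.25)
  or_planted <- or_of(1.8, 32)
  expect_gt(or_planted, 1.5); expect_lt(or_planted, 2.1)

  tr0 <- simulate_tracks(ann, rep(FALSE, 5000), 1.8, seed = 33)
  expect_lt(nrow(tr0$intervals) / 5000, 0.25)  # background only
  expect_error(simulate_tracks(ann, flags, -1, seed = 1), "enrichment_odds")
})

test_that("GWAS lists respect the overlap fraction and block budget", {
  cfg <- sim_config(n_samples = 110, n_snps = 200, seed = 41)
  g <- simulate_genotypes(cfg)
  qtl <- g$snps$snp_id[c(1, 25, 55, 85)]  # blocks 1, 3, 6, 9
  gl <- simulate_gwas_list(g, qtl, n_hits = 6, overlap_fraction = 0.5, seed = 5)
  expect_equal(nrow(gl), 6)
  expect_true(all(gl$p_value < 5e-8))
  hit_blocks <- g$snps$block[match(gl$snp_id, g$snps$snp_id)]
  qtl_blocks <- unique(g$snps$block[match(qtl, g$snps$snp_id)])
  expect_equal(sum(hit_blocks %in% qtl_blocks), 3)
  expect_identical(gl, simulate_gwas_list(g, qtl, 6, 0.5, seed = 5))
  expect_error(simulate_gwas_list(g, qtl, n_hits = 50, overlap_fraction = 1,
                                  seed = 5), "exceeds")
})

test_that("covariates have the documented marginals", {
  cv <- make_covariates(110, seed = 77)
  expect_equal(nrow(cv), 110)
  expect_false(anyNA(cv))
  expect_true(all(cv$gender %in% 0:1))
  expect_true(all(cv$age_years >= 1 & cv$age_years <= 67))
  expect_true(all(cv$neuronal_proportion >= 0.2 & cv$neuronal_proportion <= 0.8))
  expect_identical(cv, make_covariates(110, seed = 77))
  expect_error(make_covariates(1, seed = 1), "at least 2")
})
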