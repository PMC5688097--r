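resid_pm <- function(values, anchor_pos, prefix = "cg") {
  toy_probe_matrix(values, anchor_pos = anchor_pos, value_kind = "residual",
                   prefix = prefix)
}

test_that("perfect anticorrelation and the window rule behave as stated", {
  set.seed(30)
  n <- 20
  x <- scale(rnorm(n))[, 1]
  meth <- resid_pm(cbind(x, rnorm(n)), anchor_pos = c(1000L, 520000L))
  expr <- resid_pm(cbind(-x), anchor_pos = 10000L, prefix = "tx")
  rec <- correlate_cis(meth, expr, window_bp = 500000)
  # CpG at 520,000 is 510,000 bp from the expression anchor: not tested
  expect_equal(nrow(rec), 1)
  expect_equal(rec$cpg_id, "cg001")
  expect_equal(rec$pearson_r, -1, tolerance = 1e-12)
  expect_equal(rec$r_squared, 1, tolerance = 1e-12)
  expect_equal(rec$direction, -1)

  # boundary: exactly 500,000 bp is tested, 500,001 is not
  meth_b <- resid_pm(cbind(x, x), anchor_pos = c(510000L, 510001L))
  rec_b <- correlate_cis(meth_b, expr, window_bp = 500000)
  expect_equal(rec_b$cpg_id, "cg001")
})

test_that("correlation statistics match the Pearson t-transform oracle", {
  set.seed(31)
  n <- 15
  a <- rnorm(n); b <- 0.6 * a + rnorm(n)
  meth <- resid_pm(cbind(scale(a, scale = FALSE)), anchor_pos = 1000L)
  expr <- resid_pm(cbind(scale(b, scale = FALSE)), anchor_pos = 2000L,
                   prefix = "tx")
  rec <- correlate_cis(meth, expr)
  ct <- cor.test(a, b)
  expect_equal(rec$pearson_r, unname(ct$estimate), tolerance = 1e-10)
  expect_equal(rec$p_value, ct$p.value, tolerance = 1e-10)
  expect_equal(rec$r_squared, rec$pearson_r^2, tolerance = 1e-12)
})

test_that("correlating residuals equals the partial correlation", {
  set.seed(32)
  n <- 40
  covs <- data.frame(u = rnorm(n), v = rnorm(n))
  m_raw <- 0.5 * covs$u + rnorm(n)
  e_raw <- -0.4 * m_raw + 0.3 * covs$v + rnorm(n)
  mr <- residualize(matrix(m_raw), covs)
  er <- residualize(matrix(e_raw), covs)
  rec <- correlate_cis(resid_pm(mr, 1000L), resid_pm(er, 2000L, "tx"))
  # partial correlation oracle via the recursive formula on lm residuals
  pr <- cor(residuals(lm(m_raw ~ u + v, covs)),
            residuals(lm(e_raw ~ u + v, covs)))
  expect_equal(rec$pearson_r, pr, tolerance = 1e-10)
})

test_that("zero-variance residuals are skipped with a message", {
  n <- 10
  meth <- resid_pm(cbind(rep(0, n), rnorm(n)), anchor_pos = c(1000L, 1100L))
  expr <- resid_pm(cbind(rnorm(n)), anchor_pos = 2000L, prefix = "tx")
  expect_message(rec <- correlate_cis(meth, expr), "zero-variance")
  expect_equal(rec$cpg_id, "cg002")
})

test_that("shared drivers are recovered exactly on planted triples", {
  set.seed(33)
  cfg <- sim_config(n_samples = 110, n_snps = 100, ld_block_size = 10,
                    n_cpg_probes = 40, n_expr_probes = 30,
                    planted_meqtls = data.frame(snp = c(5, 25, 45, 65, 85),
                                                probe = 1:5,
                                                variance_explained = rep(0.55, 5)),
                    planted_eqtls = data.frame(snp = c(5, 25, 45, 75, 95),
                                               probe = 1:5,
                                               variance_explained = rep(0.5, 5)),
                    seed = 34)
  co <- simulate_cohort(cfg)
  covs <- co$covariates
  scan_m <- run_cis_scan(co$genotypes, co$methylation, covs, scan_config())
  scan_e <- run_cis_scan(co$genotypes, co$expression, covs, scan_config())
  mr <- residualize(co$methylation, covs)
  er <- residualize(co$expression, covs)
  corr <- correlate_cis(mr, er)
  drivers <- find_shared_drivers(scan_m$records, scan_e$records, corr,
                                 co$genotypes, r2_min = 0.4)
  # probes 1-3 share SNPs (5, 25, 45); 4-5 have independent drivers
  shared_cpgs <- attr(co$methylation, "planted")$probe_id[1:3]
  indep_cpgs <- attr(co$methylation, "planted")$probe_id[4:5]
  found <- unique(drivers$cpg_id)
  expect_true(all(found %in% shared_cpgs))
  expect_false(any(indep_cpgs %in% found))
  if (nrow(drivers)) expect_true(all(drivers$r2_between_snps >= 0.4))
})

test_that("same-SNP drivers give r2 = 1 and unlinked drivers are dropped", {
  set.seed(35)
  n <- 110
  d1 <- rbinom(n, 2, 0.3)
  d2 <- rbinom(n, 2, 0.4)  # independent of d1
  g <- toy_genotypes(cbind(d1, d2), pos = c(1000L, 5000L))
  mk_rec <- function(snp, probe) {
    data.frame(snp_id = snp, probe_id = probe, snp_pos = 1000,
               p = 1e-10, fdr_significant = TRUE)
  }
  corr <- data.frame(cpg_id = "cgA", expr_probe_id = "txA",
                     cpg_chrom = "chr1", cpg_pos = 1000, distance_bp = 0,
                     pearson_r = -0.9, r_squared = 0.81, p_value = 1e-8,
                     fdr_significant = TRUE, direction = -1)
  same <- find_shared_drivers(mk_rec("snp001", "cgA"), mk_rec("snp001", "txA"),
                              corr, g)
  expect_equal(nrow(same), 1)
  expect_equal(same$r2_between_snps, 1)
  diff <- find_shared_drivers(mk_rec("snp001", "cgA"), mk_rec("snp002", "txA"),
                              corr, g)
  expect_equal(nrow(diff), 0)
})

test_that("direction summary counts and Fisher OR follow the 2x2 table", {
  mk <- function(r, pos) {
    data.frame(cpg_id = sprintf("cg%03d", seq_along(r)), expr_probe_id = "tx",
               cpg_chrom = "chr1", cpg_pos = pos, distance_bp = 0,
               pearson_r = r, r_squared = r^2, p_value = 1e-5,
               fdr_significant = TRUE, direction = sign(r))
  }
  prom <- interval_track("promoters",
                         data.frame(chrom = "chr1", start = 0, end = 1000))
  all_neg <- mk(rep(-0.5, 6), pos = rep(c(500, 5000), 3))
  s1 <- direction_summary(all_neg, prom)
  expect_equal(s1$fraction_negative, 1)

  # balanced table: OR = 1
  bal <- mk(c(rep(-0.5, 10), rep(0.5, 10)),
            pos = rep(c(rep(500, 5), rep(5000, 5)), 2))
  s2 <- direction_summary(bal, prom)
  expect_equal(s2$fisher$odds_ratio, 1)

  # constructed table (3 neg-in, 27 pos-in; 14 neg-out, 16 pos-out)
  con <- mk(c(rep(-1, 3), rep(1, 27), rep(-1, 14), rep(1, 16)) * 0.5,
            pos = c(rep(500, 30), rep(5000, 30)))
  s3 <- direction_summary(con, prom)
  expect_equal(s3$fisher$odds_ratio, (3 * 16) / (27 * 14), tolerance = 1e-12)
})
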