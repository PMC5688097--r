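test_that("cis pairing is inclusive at the window boundary", {
  snp <- data.frame(snp_id = "s1", chrom = "chr1", pos = 1000000L)
  probe_in <- data.frame(probe_id = "p1", chrom = "chr1", anchor_pos = 1500000L)
  probe_out <- data.frame(probe_id = "p2", chrom = "chr1", anchor_pos = 1500001L)
  probe_chr <- data.frame(probe_id = "p3", chrom = "chr2", anchor_pos = 1000000L)
  expect_equal(nrow(enumerate_cis_pairs(snp, probe_in, 500000)), 1)
  expect_equal(nrow(enumerate_cis_pairs(snp, probe_out, 500000)), 0)
  expect_equal(nrow(enumerate_cis_pairs(snp, probe_chr, 500000)), 0)
})

test_that("sweep enumeration matches the brute-force double loop", {
  snp <- data.frame(snp_id = sprintf("s%02d", 1:10), chrom = "chr1",
                    pos = as.integer(seq(100000, by = 100000, length.out = 10)))
  probe <- data.frame(probe_id = "p1", chrom = "chr1", anchor_pos = 550000L)
  pairs <- enumerate_cis_pairs(snp, probe, 500000)
  brute <- expand.grid(i = 1:10, j = 1)
  brute <- brute[abs(snp$pos[brute$i] - probe$anchor_pos[brute$j]) <= 500000, ]
  expect_setequal(pairs$snp_id, snp$snp_id[brute$i])
  expect_equal(pairs$distance_bp,
               abs(snp$pos[pairs$snp_idx] - probe$anchor_pos))

  # larger random check
  set.seed(14)
  snp2 <- data.frame(snp_id = sprintf("s%03d", 1:80),
                     chrom = sample(c("chr1", "chr2"), 80, TRUE),
                     pos = sample.int(3000000L, 80))
  probe2 <- data.frame(probe_id = sprintf("p%03d", 1:40),
                       chrom = sample(c("chr1", "chr2"), 40, TRUE),
                       anchor_pos = sample.int(3000000L, 40))
  pairs2 <- enumerate_cis_pairs(snp2, probe2, 400000)
  brute2 <- expand.grid(i = 1:80, j = 1:40)
  brute2 <- brute2[snp2$chrom[brute2$i] == probe2$chrom[brute2$j] &
                     abs(snp2$pos[brute2$i] - probe2$anchor_pos[brute2$j]) <= 400000, ]
  key <- function(s, p) paste(s, p)
  expect_setequal(key(pairs2$snp_id, pairs2$probe_id),
                  key(snp2$snp_id[brute2$i], probe2$probe_id[brute2$j]))
})

test_that("genotype PCs separate divergent subpopulations", {
  set.seed(15)
  n <- 60
  p1 <- runif(40, 0.1, 0.3)
  p2 <- p1 + 0.4
  d <- rbind(sapply(p1, function(p) rbinom(n / 2, 2, p)),
             sapply(p2, function(p) rbinom(n / 2, 2, p)))
  g <- toy_genotypes(d)
  pcs <- compute_genotype_pcs(g, 3)
  grp <- rep(c(1, 2), each = n / 2)
  between <- abs(mean(pcs$genoPC1[grp == 1]) - mean(pcs$genoPC1[grp == 2]))
  within <- max(sd(pcs$genoPC1[grp == 1]), sd(pcs$genoPC1[grp == 2]))
  expect_gt(between, within)
  # orthogonal scores
  expect_lt(abs(sum(pcs$genoPC1 * pcs$genoPC2)), 1e-6)
  # sign flips leave regression fits unchanged
  y <- rnorm(n)
  f1 <- fit_additive_model(y, d[, 1], pcs)
  pcs_f <- pcs; pcs_f$genoPC1 <- -pcs_f$genoPC1
  f2 <- fit_additive_model(y, d[, 1], pcs_f)
  expect_equal(f1$p, f2$p, tolerance = 1e-12)
})

test_that("residualize projects out the covariates exactly", {
  set.seed(16)
  n <- 12
  covs <- data.frame(a = rnorm(n), b = rnorm(n))
  y_equal <- 2 + 3 * covs$a
  r1 <- residualize(matrix(y_equal), covs)
  expect_lt(max(abs(r1)), 1e-10)

  y <- rnorm(n)
  X <- cbind(1, as.matrix(covs))
  P <- X %*% solve(crossprod(X)) %*% t(X)
  expect_equal(as.numeric(residualize(matrix(y), covs)),
               as.numeric((diag(n) - P) %*% y), tolerance = 1e-10)

  # orthogonal (after centering) response comes back centered
  yo <- residuals(lm(rnorm(n) ~ X - 1))
  expect_equal(as.numeric(residualize(matrix(yo), covs)), as.numeric(yo),
               tolerance = 1e-10)

  covs_bad <- data.frame(a = covs$a, b = 2 * covs$a)
  expect_error(residualize(matrix(y), covs_bad), "collinear")
})

test_that("hidden-confounder PCs find a planted latent factor", {
  set.seed(17)
  n <- 50
  factor <- rnorm(n)
  vals <- outer(factor, runif(500, 0.5, 1)) + matrix(rnorm(n * 500, sd = 0.5), n, 500)
  pcs <- hidden_confounder_pcs(vals, 3)
  vp <- attr(pcs, "variance_proportion")
  expect_true(all(diff(vp) <= 1e-12))
  expect_lte(max(vp), 1)
  expect_gt(abs(cor(pcs$hiddenPC1, factor)), 0.9)
  sv <- svd(scale(vals, center = TRUE, scale = FALSE))
  expect_equal(abs(cor(pcs$hiddenPC2, sv$u[, 2])), 1, tolerance = 1e-8)
  expect_error(hidden_confounder_pcs(vals[1:4, ], 5), "rank")
})

test_that("the additive model matches the closed-form OLS oracle", {
  # exact relationship: zero residual
  d <- c(0, 1, 2, 0, 1, 2, 0, 1, 2, 1)
  f <- fit_additive_model(0.05 * d, d)
  expect_equal(f$beta, 0.05, tolerance = 1e-12)
  expect_equal(f$se, 0, tolerance = 1e-10)

  expect_null(suppressMessages(fit_additive_model(rnorm(10), rep(1, 10))))

  # 12-sample toy with one covariate against lm()
  set.seed(18)
  n <- 12
  g <- rbinom(n, 2, 0.4)
  cv <- data.frame(age = rnorm(n, 40, 10))
  y <- 0.3 * g + 0.01 * cv$age + rnorm(n)
  ours <- fit_additive_model(y, g, cv)
  ref <- summary(lm(y ~ g + age, data = cv))$coefficients["g", ]
  expect_equal(ours$beta, unname(ref["Estimate"]), tolerance = 1e-8)
  expect_equal(ours$se, unname(ref["Std. Error"]), tolerance = 1e-8)
  expect_equal(ours$t, unname(ref["t value"]), tolerance = 1e-8)
  expect_equal(ours$p, unname(ref["Pr(>|t|)"]), tolerance = 1e-8)
})

test_that("BH step-up matches brute-force evaluation", {
  expect_false(any(bh_fdr(rep(1, 5), 0.01)$significant))
  expect_true(bh_fdr(0.005, 0.01)$significant)

  p <- c(0.001, 0.002, 0.009, 0.5)
  res <- bh_fdr(p, 0.01)
  # brute-force step-up: largest k with p_(k) <= k/m * alpha
  m <- length(p)
  ps <- sort(p)
  k <- max(c(0, which(ps <= seq_len(m) / m * 0.01)))
  brute <- p <= if (k == 0) -1 else ps[k]
  expect_equal(res$significant, brute)
  expect_equal(res$p_threshold, max(p[brute]))

  set.seed(19)
  for (i in 1:20) {
    p <- runif(50)^sample(1:4, 1)
    res <- bh_fdr(p, 0.05)
    ps <- sort(p)
    k <- max(c(0, which(ps <= seq_len(50) / 50 * 0.05)))
    brute <- p <= if (k == 0) -1 else ps[k]
    expect_equal(res$significant, brute)
  }
})

test_that("variance decomposition sums for orthogonal designs and recovers nulls", {
  set.seed(20)
  n <- 64
  # orthonormal mean-zero columns (orthogonal to the intercept too)
  X <- qr.Q(qr(scale(matrix(rnorm(n * 3), n, 3), center = TRUE, scale = FALSE)))
  g <- X[, 1]; c1 <- X[, 2]; c2 <- X[, 3]
  y <- 2 * g + 1 * c1 + 0.5 * c2 + rnorm(n, sd = 0.5)
  covs <- data.frame(c1 = c1, c2 = c2)
  sh <- variance_decomposition(y, g, covs)
  full <- summary(lm(y ~ g + c1 + c2))$r.squared
  expect_equal(unname(sum(sh)), full, tolerance = 1e-10)

  # independence: share of an unrelated covariate vanishes at large n
  set.seed(21)
  n2 <- 2000
  g2 <- rbinom(n2, 2, 0.3)
  covs2 <- data.frame(noise = rnorm(n2))
  y2 <- 0.2 * g2 + rnorm(n2)
  sh2 <- variance_decomposition(y2, g2, covs2)
  expect_lt(abs(sh2[["noise"]]), 0.01)
})

test_that("a 1x1 scan equals the single-pair model fit verbatim", {
  set.seed(22)
  n <- 80
  d <- rbinom(n, 2, 0.4)
  y <- 0.1 * d + rnorm(n, sd = 0.3)
  covs <- make_covariates(n, seed = 1)
  g <- toy_genotypes(cbind(d), pos = 1000L)
  pm <- toy_probe_matrix(matrix(plogis(y)), anchor_pos = 2000L)
  scan <- run_cis_scan(g, pm, covs, scan_config())
  ref <- fit_additive_model(pm$values[, 1], d, covs)
  expect_equal(scan$records$beta, ref$beta, tolerance = 1e-10)
  expect_equal(scan$records$se, ref$se, tolerance = 1e-10)
  expect_equal(scan$records$t, ref$t, tolerance = 1e-10)
  expect_equal(scan$records$p, ref$p, tolerance = 1e-10)
})

test_that("the vectorized scan equals per-pair OLS on a random cohort", {
  co <- planted_cohort(n = 60, seed = 23)
  covs <- co$covariates
  scan <- run_cis_scan(co$genotypes, co$methylation, covs,
                       scan_config(window_bp = 100000))
  rec <- scan$records
  set.seed(24)
  for (i in sample.int(nrow(rec), 12)) {
    y <- co$methylation$values[, rec$probe_id[i]]
    d <- co$genotypes$dosage[, rec$snp_id[i]]
    ref <- fit_additive_model(y, d, covs)
    expect_equal(rec$beta[i], ref$beta, tolerance = 1e-8)
    expect_equal(rec$p[i], ref$p, tolerance = 1e-8)
  }
})

test_that("scan results are invariant to input order", {
  co <- planted_cohort(n = 50, seed = 25)
  covs <- co$covariates
  s1 <- run_cis_scan(co$genotypes, co$methylation, covs,
                     scan_config(window_bp = 50000))
  perm <- sample(ncol(co$genotypes$dosage))
  gp <- genotype_matrix(co$genotypes$samples,
                        co$genotypes$snps[perm, ],
                        co$genotypes$dosage[, perm])
  s2 <- run_cis_scan(gp, co$methylation, covs, scan_config(window_bp = 50000))
  key <- function(r) r[order(r$snp_id, r$probe_id), c("snp_id", "probe_id", "beta", "p")]
  expect_equal(key(s1$records), key(s2$records), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("r2_genotype equals t^2/(t^2+df) without covariates", {
  set.seed(26)
  n <- 40
  d <- rbinom(n, 2, 0.3)
  g <- toy_genotypes(cbind(d), pos = 1000L)
  pm <- toy_probe_matrix(matrix(runif(n)), anchor_pos = 1500L)
  scan <- run_cis_scan(g, pm, NULL, scan_config(decompose = "all"))
  rec <- scan$records
  expect_equal(rec$r2_genotype, rec$t^2 / (rec$t^2 + (n - 2)),
               tolerance = 1e-10)
})

test_that("methylation effect sizes stay within the beta scale", {
  co <- planted_cohort(n = 110, seed = 27)
  scan <- run_cis_scan(co$genotypes, co$methylation, co$covariates,
                       scan_config())
  sig <- scan$records[scan$records$fdr_significant, ]
  expect_true(all(abs(sig$beta) <= 1))
  expect_true(all(sig$distance_bp <= 500000))
  expect_true(all(sig$p > 0 & sig$p <= 1))
})

test_that("planted cohorts are recovered by the scan", {
  co <- planted_cohort(n = 110, seed = 28, v = c(0.3, 0.6))
  scan <- run_cis_scan(co$genotypes, co$methylation, co$covariates,
                       scan_config())
  sig_probes <- unique(scan$records$probe_id[scan$records$fdr_significant])
  expect_true(all(co$truth_meqtl$probe_id %in% sig_probes))
  # decomposed genotype share near the planted fraction for the top SNP
  rec <- scan$records[scan$records$fdr_significant, ]
  for (k in seq_len(nrow(co$truth_meqtl))) {
    sub <- rec[rec$probe_id == co$truth_meqtl$probe_id[k], ]
    top <- sub[which.min(sub$p), ]
    expect_lt(abs(top$r2_genotype - co$truth_meqtl$variance_explained[k]), 0.12)
  }
})

test_that("misaligned samples abort before any fitting", {
  co <- planted_cohort(n = 30, seed = 29)
  pm_bad <- co$methylation
  pm_bad$samples <- rev(pm_bad$samples)
  expect_error(run_cis_scan(co$genotypes, pm_bad, co$covariates),
               "misalignment")
  covs_bad <- co$covariates[rev(rownames(co$covariates)), ]
  expect_error(run_cis_scan(co$genotypes, co$methylation, covs_bad),
               "misalignment")
})
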