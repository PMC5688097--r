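# independent HWE oracle: enumerate every genotype table compatible with
# the observed allele counts and normalize exact conditional probabilities
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n - nA
  if (nA == 0 || na == 0) return(1)
  configs <- list()
  for (h in 0:min(nA, na)) {
    if ((min(nA, na) - h) %% 2 != 0) next
    aa <- (na - h) / 2
    AA <- (nA - h) / 2
    if (aa < 0 || AA < 0 || AA + h + aa != n) next
    configs[[length(configs) + 1]] <- c(AA = AA, h = h, aa = aa)
  }
  w <- vapply(configs, function(cf) {
    exp(lfactorial(n) - lfactorial(cf[1]) - lfactorial(cf[2]) - lfactorial(cf[3]) +
          cf[2] * log(2))
  }, numeric(1))
  pr <- w / sum(w)
  obs <- pr[vapply(configs, function(cf) cf[2] == n_Aa, logical(1))]
  sum(pr[pr <= obs + 1e-12])
}

test_that("exact HWE p matches enumeration and conventions", {
  expect_equal(hwe_exact_p(0, 2, 0), 1)
  expect_equal(hwe_exact_p(100, 0, 0), 1)   # monomorphic convention
  expect_equal(hwe_exact_p(5, 0, 5), hwe_oracle(5, 0, 5), tolerance = 1e-12)
  # randomized sweep against the enumeration oracle
  set.seed(4)
  for (i in 1:40) {
    cnt <- as.vector(rmultinom(1, sample(5:60, 1), prob = runif(3)))
    expect_equal(hwe_exact_p(cnt[1], cnt[2], cnt[3]),
                 hwe_oracle(cnt[1], cnt[2], cnt[3]), tolerance = 1e-10,
                 info = paste(cnt, collapse = ","))
  }
  # balanced table is modal
  expect_equal(hwe_exact_p(25, 50, 25), 1, tolerance = 1e-9)
})

test_that("SNP QC removes by first failing rule and conserves counts", {
  set.seed(2)
  n <- 100
  good1 <- rbinom(n, 2, 0.3)
  good2 <- rbinom(n, 2, 0.4)
  low_cr <- rbinom(n, 2, 0.3); low_cr[1:10] <- NA          # 90% call rate
  low_maf <- c(rep(1, 2), rep(0, n - 2))                    # maf = 0.01
  bad_hwe <- rep(c(0, 2), n / 2)                            # no hets
  g <- toy_genotypes(cbind(good1, low_cr, low_maf, bad_hwe, good2))
  res <- snp_qc(g, call_rate_min = 0.97, maf_min = 0.05, hwe_p_min = 1e-6)
  expect_equal(res$report$n_output, 2)
  expect_equal(res$genotypes$snps$snp_id, c("snp001", "snp005"))
  expect_equal(unname(res$report$n_removed_per_rule["call_rate"]), 1)
  expect_equal(unname(res$report$n_removed_per_rule["maf"]), 1)
  expect_equal(unname(res$report$n_removed_per_rule["hwe"]), 1)
  expect_equal(res$report$n_input,
               sum(res$report$n_removed_per_rule) + res$report$n_output)

  # order independence of the kept set
  perm <- c(4, 2, 5, 1, 3)
  gp <- toy_genotypes(g$dosage[, perm], pos = g$snps$pos[perm])
  resp <- snp_qc(gp, 0.97, 0.05, 1e-6)
  expect_equal(sort(match(resp$genotypes$snps$snp_id, gp$snps$snp_id)),
               sort(which(perm %in% c(1, 5))))
})

test_that("HWE-balanced SNP is kept", {
  g <- toy_genotypes(cbind(c(rep(0, 25), rep(1, 50), rep(2, 25))))
  res <- snp_qc(g, 0.97, 0.05, 1e-6)
  expect_equal(res$report$n_output, 1)
})

test_that("CpG probe filter applies the five-rule cascade", {
  n <- 100
  np <- 10
  set.seed(3)
  beta <- matrix(runif(n * np), n, np)
  det <- matrix(0, n, np)
  beads <- matrix(10, n, np)
  det[1:6, 1] <- 0.02           # rule i: 6% of samples above p 0.01
  beads[1:5, 2] <- 2            # rule ii: 5% of samples below 3 beads
  pm <- toy_probe_matrix(beta, anchor_pos = c(rep(5000L, 9), 600001L))
  snp_ann <- data.frame(chrom = "chr1", pos = 100000L)
  res <- filter_cpg_probes(pm, detection_p = det, bead_counts = beads,
                           crosshyb_list = "p003", snp_probe_list = "p004",
                           snp_annotation = snp_ann, cis_window = 500000)
  # probe 10 sits 500,001 bp from the only SNP -> rule v
  expect_equal(res$report$n_output, 5)
  expect_equal(unname(res$report$n_removed_per_rule),
               c(1, 1, 1, 1, 1))
  expect_equal(res$probes$probes$probe_id,
               sprintf("p%03d", 5:9))

  # boundary: exactly 500,000 bp away counts as present
  pm2 <- toy_probe_matrix(beta[, 1, drop = FALSE], anchor_pos = 600000L)
  res2 <- filter_cpg_probes(pm2, snp_annotation = snp_ann)
  expect_equal(res2$report$n_output, 1)
  pm3 <- toy_probe_matrix(beta[, 1, drop = FALSE], anchor_pos = 600001L)
  res3 <- filter_cpg_probes(pm3, snp_annotation = snp_ann)
  expect_equal(res3$report$n_output, 0)
})

test_that("expression probe filter drops weak and listed probes", {
  n <- 100
  set.seed(8)
  vals <- matrix(rnorm(n * 6, 8), n, 6)
  det <- matrix(0.01, n, 6)
  det[, 1] <- 0.5                        # detected nowhere
  det[1:96, 2] <- 0.5                    # detected in 4% of samples only
  pm <- toy_probe_matrix(vals, value_kind = "log2_expression")
  res <- filter_expression_probes(pm, detection_p = det,
                                  crosshyb_list = "p003")
  expect_equal(res$report$n_output, 3)
  expect_equal(res$probes$probes$probe_id, sprintf("p%03d", 4:6))
  expect_equal(res$report$n_input,
               sum(res$report$n_removed_per_rule) + res$report$n_output)
})

test_that("quantile normalization matches the order-statistic construction", {
  # identical distributions: unchanged
  x <- matrix(rep(c(1, 3, 2, 5), 2), 2, 4, byrow = TRUE)
  expect_equal(quantile_normalize(x), x)

  # 3 samples x 4 probes hand oracle
  y <- rbind(c(2, 4, 6, 8),
             c(1, 2, 3, 4),
             c(10, 30, 20, 40))
  ref <- (sort(y[1, ]) + sort(y[2, ]) + sort(y[3, ])) / 3
  hand <- t(apply(y, 1, function(v) ref[rank(v)]))
  expect_equal(quantile_normalize(y), hand)

  # post-condition: all samples share the sorted vector
  set.seed(5)
  z <- matrix(rnorm(8 * 30), 8, 30)
  qz <- quantile_normalize(z)
  sorted <- t(apply(qz, 1, sort))
  expect_equal(max(abs(sweep(sorted, 2, sorted[1, ]))), 0, tolerance = 1e-12)

  # idempotence
  expect_equal(quantile_normalize(qz), qz, tolerance = 1e-10)

  # subsets are normalized independently
  qs <- quantile_normalize(z, column_subsets = list(1:15, 16:30))
  expect_equal(qs[, 1:15], quantile_normalize(z[, 1:15]))
  expect_false(isTRUE(all.equal(qs, qz)))
})

test_that("quantile normalization agrees with the limma reference", {
  skip_if_not_installed("limma")
  set.seed(6)
  z <- matrix(rnorm(10 * 50), 10, 50)
  ours <- quantile_normalize(z)
  # limma normalizes columns; our samples are rows
  ref <- t(limma::normalizeQuantiles(t(z), ties = TRUE))
  expect_equal(ours, ref, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("quantile normalization preserves missing values", {
  set.seed(7)
  z <- matrix(rnorm(6 * 20), 6, 20)
  z[cbind(c(1, 3), c(5, 12))] <- NA
  qz <- quantile_normalize(z)
  expect_true(all(is.na(qz[cbind(c(1, 3), c(5, 12))])))
  expect_false(anyNA(qz[-c(1, 3), ]))
})

test_that("log2 offset transform hits the anchor points", {
  expect_equal(log2_offset_transform(matrix(0)), matrix(4))
  expect_equal(log2_offset_transform(matrix(16)), matrix(5))
  expect_equal(log2_offset_transform(matrix(48)), matrix(6))
  expect_error(log2_offset_transform(matrix(-16)), "log2")
})

test_that("control-probe PCs reproduce the SVD and order variance", {
  set.seed(9)
  # rank-1 matrix: PC1 carries all variance
  u <- rnorm(20); v <- rnorm(50)
  r1 <- outer(u, v)
  pcs1 <- control_probe_pcs(r1, n_pcs = 2)
  vp <- attr(pcs1, "variance_proportion")
  expect_gt(vp[1], 0.999999)

  x <- matrix(rnorm(20 * 50), 20, 50)
  pcs <- control_probe_pcs(x, n_pcs = 6)
  sv <- svd(scale(x, center = TRUE, scale = FALSE))
  for (k in 1:6) {
    expect_equal(abs(cor(pcs[[k]], sv$u[, k] * sv$d[k])), 1, tolerance = 1e-8)
  }
  expect_true(all(diff(attr(pcs, "variance_proportion")) <= 1e-12))
  expect_error(control_probe_pcs(x[1:3, ], n_pcs = 6), "fewer samples")
})
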