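# SNP and probe quality control plus normalization transforms for
# 450K-style methylation and HT-12-style expression matrices.
#
# Filter attribution is always "first failing rule" in the documented rule
# order, so QC reports are reproducible and counts are conserved.

#' QC report constructor
#'
#' @param stage label of the QC stage.
#' @param n_input number of features before filtering.
#' @param n_removed_per_rule named integer vector; each feature is counted
#'   under the first rule it fails.
#' @return list of class \code{qc_report}; construction fails unless
#'   \code{n_input - sum(removed) == n_output}.
#' @export
qc_report <- function(stage, n_input, n_removed_per_rule) {
  n_output <- n_input - sum(n_removed_per_rule)
  if (n_output < 0) stop("QC report does not conserve counts")
  structure(list(stage = stage, n_input = n_input,
                 n_removed_per_rule = n_removed_per_rule,
                 n_output = n_output),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC stage '%s': %d -> %d\n", x$stage, x$n_input, x$n_output))
  for (nm in names(x$n_removed_per_rule)) {
    cat(sprintf("  removed by %s: %d\n", nm, x$n_removed_per_rule[[nm]]))
  }
  invisible(x)
}

# first failing rule per feature; `fails` is a logical matrix
# (features x rules, column order = rule priority)
first_failing <- function(fails) {
  idx <- apply(fails, 1, function(r) {
    w <- which(r)
    if (length(w)) w[1] else NA_integer_
  })
  idx
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact conditional test: given the allele counts, the p-value
#' is the sum of the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed table.
#' Monomorphic SNPs return p = 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa non-negative genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("negative genotype count")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("need at least one genotype")
  n_a <- 2 * n_aa + n_Aa            # minor-ish allele count (either works)
  n_A <- 2 * n_AA + n_Aa
  if (n_a == 0 || n_A == 0) return(1)
  rare <- min(n_a, n_A)
  hets <- seq(rare %% 2, rare, by = 2)  # feasible heterozygote counts
  # unnormalized conditional probabilities P(n_Aa = h | allele counts)
  logp <- vapply(hets, function(h) {
    n_rr <- (rare - h) / 2
    n_cc <- n - h - n_rr  # common homozygotes
    lgamma(n + 1) - lgamma(n_rr + 1) - lgamma(h + 1) - lgamma(n_cc + 1) +
      h * log(2)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  if (is.na(obs)) stop("observed heterozygote count infeasible for allele counts")
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

#' SNP quality control
#'
#' Keeps a SNP iff call rate > \code{call_rate_min}, MAF >
#' \code{maf_min} and exact HWE p > \code{hwe_p_min}; removals are
#' attributed to the first failing rule in that order.
#'
#' @param genotypes a \code{\link{genotype_matrix}} of hard calls (dosages
#'   are rounded for the HWE genotype counts).
#' @param call_rate_min,maf_min,hwe_p_min thresholds in (0, 1).
#' @return list(genotypes, report).
#' @export
snp_qc <- function(genotypes, call_rate_min = 0.97, maf_min = 0.05,
                   hwe_p_min = 1e-6) {
  d <- genotypes$dosage
  call_rate <- colMeans(!is.na(d))
  maf <- genotypes$snps$maf
  hwe <- apply(d, 2, function(col) {
    g <- round(col[!is.na(col)])
    hwe_exact_p(sum(g == 0), sum(g == 1), sum(g == 2))
  })
  fails <- cbind(call_rate = !(call_rate > call_rate_min),
                 maf = !(maf > maf_min),
                 hwe = !(hwe > hwe_p_min))
  rule <- first_failing(fails)
  keep <- is.na(rule)
  removed <- c(call_rate = sum(rule == 1, na.rm = TRUE),
               maf = sum(rule == 2, na.rm = TRUE),
               hwe = sum(rule == 3, na.rm = TRUE))
  report <- qc_report("snp_qc", ncol(d), removed)
  if (!any(keep)) {
    warning("all SNPs removed by QC")
    out <- genotype_matrix(genotypes$samples,
                           genotypes$snps[integer(0), , drop = FALSE],
                           d[, integer(0), drop = FALSE])
    return(list(genotypes = out, report = report))
  }
  out <- genotype_matrix(genotypes$samples,
                         genotypes$snps[keep, , drop = FALSE],
                         d[, keep, drop = FALSE])
  list(genotypes = out, report = report)
}

#' Filter CpG methylation probes
#'
#' Applies the five-rule exclusion cascade for 450K-style beta matrices:
#' (i) detection p > 0.01 in at least 5\% of samples, (ii) bead count < 3
#' in at least 5\% of samples, (iii) probe on the cross-hybridization
#' list, (iv) probe on the SNP-in-probe list, (v) no SNP of the supplied
#' annotation within the cis window (+/- 500 kb, boundary inclusive) of
#' the CpG. Rules with a NULL companion input are skipped; a probe is
#' counted under the first rule it fails.
#'
#' @param beta_matrix a beta-value \code{\link{probe_matrix}}.
#' @param detection_p optional samples x probes matrix of detection
#'   p-values.
#' @param bead_counts optional samples x probes matrix of bead counts.
#' @param crosshyb_list,snp_probe_list optional character vectors of probe
#'   ids to exclude.
#' @param snp_annotation optional SNP annotation data.frame (chrom, pos)
#'   enabling rule (v).
#' @param cis_window half-width of the cis window in bp.
#' @param detection_p_max,detection_frac,bead_min,bead_frac rule
#'   thresholds.
#' @return list(probes = filtered \code{\link{probe_matrix}}, report).
#' @export
filter_cpg_probes <- function(beta_matrix, detection_p = NULL,
                              bead_counts = NULL, crosshyb_list = NULL,
                              snp_probe_list = NULL, snp_annotation = NULL,
                              cis_window = 500000,
                              detection_p_max = 0.01, detection_frac = 0.05,
                              bead_min = 3, bead_frac = 0.05) {
  np <- nrow(beta_matrix$probes)
  ids <- beta_matrix$probes$probe_id
  check_companion <- function(m, what) {
    if (!is.null(m) && (nrow(m) != length(beta_matrix$samples) ||
                        ncol(m) != np)) {
      stop(what, " matrix does not conform to the beta matrix")
    }
  }
  check_companion(detection_p, "detection p")
  check_companion(bead_counts, "bead count")
  r_det <- if (is.null(detection_p)) rep(FALSE, np) else {
    colMeans(detection_p > detection_p_max) >= detection_frac
  }
  r_bead <- if (is.null(bead_counts)) rep(FALSE, np) else {
    colMeans(bead_counts < bead_min) >= bead_frac
  }
  r_xhyb <- ids %in% (crosshyb_list %||% character(0))
  r_snp <- ids %in% (snp_probe_list %||% character(0))
  r_nosnp <- if (is.null(snp_annotation)) rep(FALSE, np) else {
    !has_snp_within(beta_matrix$probes, snp_annotation, cis_window)
  }
  fails <- cbind(detection_p = r_det, bead_count = r_bead,
                 cross_hybridization = r_xhyb, snp_in_probe = r_snp,
                 no_cis_snp = r_nosnp)
  rule <- first_failing(fails)
  keep <- is.na(rule)
  removed <- vapply(seq_len(ncol(fails)), function(k) sum(rule == k, na.rm = TRUE),
                    integer(1))
  names(removed) <- colnames(fails)
  report <- qc_report("cpg_filter", np, removed)
  out <- probe_matrix(beta_matrix$samples,
                      beta_matrix$probes[keep, , drop = FALSE],
                      beta_matrix$values[, keep, drop = FALSE],
                      beta_matrix$value_kind)
  list(probes = out, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# TRUE iff a probe has >= 1 SNP on the same chromosome within +/- window bp
# of its anchor (inclusive boundary)
has_snp_within <- function(probe_ann, snp_ann, window_bp) {
  out <- logical(nrow(probe_ann))
  for (ch in unique(probe_ann$chrom)) {
    sp <- sort(snp_ann$pos[snp_ann$chrom == ch])
    pi <- which(probe_ann$chrom == ch)
    if (!length(sp)) next
    nearest <- findInterval(probe_ann$anchor_pos[pi], sp)
    lo <- pmax(nearest, 1)
    hi <- pmin(nearest + 1, length(sp))
    d <- pmin(abs(probe_ann$anchor_pos[pi] - sp[lo]),
              abs(probe_ann$anchor_pos[pi] - sp[hi]))
    out[pi] <- d <= window_bp
  }
  out
}

#' Filter expression probes
#'
#' Removes weakly expressed probes (detection p above
#' \code{detection_p_max} in at least \code{weak_frac} of samples) and
#' probes on either exclusion list; attribution is first-failing-rule in
#' the order weak expression, cross-hybridization, SNP-in-probe.
#'
#' @param expr_matrix an expression \code{\link{probe_matrix}}.
#' @param detection_p samples x probes matrix of detection p-values.
#' @param crosshyb_list,snp_probe_list optional probe-id vectors.
#' @param detection_p_max,weak_frac thresholds (defaults: p > 0.05 in
#'   >= 95\% of samples).
#' @return list(probes, report).
#' @export
filter_expression_probes <- function(expr_matrix, detection_p = NULL,
                                     crosshyb_list = NULL,
                                     snp_probe_list = NULL,
                                     detection_p_max = 0.05,
                                     weak_frac = 0.95) {
  np <- nrow(expr_matrix$probes)
  ids <- expr_matrix$probes$probe_id
  if (!is.null(detection_p) &&
      (nrow(detection_p) != length(expr_matrix$samples) ||
       ncol(detection_p) != np)) {
    stop("detection p matrix does not conform to the expression matrix")
  }
  r_weak <- if (is.null(detection_p)) rep(FALSE, np) else {
    colMeans(detection_p > detection_p_max) >= weak_frac
  }
  fails <- cbind(weak_expression = r_weak,
                 cross_hybridization = ids %in% (crosshyb_list %||% character(0)),
                 snp_in_probe = ids %in% (snp_probe_list %||% character(0)))
  rule <- first_failing(fails)
  keep <- is.na(rule)
  removed <- vapply(seq_len(ncol(fails)), function(k) sum(rule == k, na.rm = TRUE),
                    integer(1))
  names(removed) <- colnames(fails)
  report <- qc_report("expression_filter", np, removed)
  out <- probe_matrix(expr_matrix$samples,
                      expr_matrix$probes[keep, , drop = FALSE],
                      expr_matrix$values[, keep, drop = FALSE],
                      expr_matrix$value_kind)
  list(probes = out, report = report)
}

#' Quantile normalization over probe subsets
#'
#' Within each probe subset, every sample's values are replaced by the
#' mean order statistic across samples at the same rank; ties receive the
#' average of their ranks' reference values. Missing values are excluded
#' from ranking and restored as missing (reference quantiles are
#' interpolated when samples differ in their number of observed values).
#' This generic form covers both single-subset expression normalization
#' and the six probe-type subsets used for Infinium intensities.
#'
#' @param mat samples x probes numeric matrix.
#' @param column_subsets optional list of probe-index (or probe-name)
#'   vectors partitioning the columns; default: one subset = all columns.
#' @return normalized matrix of the same shape.
#' @export
quantile_normalize <- function(mat, column_subsets = NULL) {
  if (is.null(column_subsets)) column_subsets <- list(seq_len(ncol(mat)))
  out <- mat
  for (s in column_subsets) {
    if (is.character(s)) s <- match(s, colnames(mat))
    if (length(s) < 2) {
      warning("quantile normalization subset with < 2 probes left unchanged")
      next
    }
    out[, s] <- qn_core(mat[, s, drop = FALSE])
  }
  out
}

qn_core <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  counts <- rowSums(!is.na(x))
  m_full <- max(counts)
  # reference distribution: mean across samples of the order statistics,
  # on a common grid of m_full quantile levels
  grid <- if (m_full == 1) 0.5 else (seq_len(m_full) - 1) / (m_full - 1)
  ref_acc <- numeric(m_full)
  for (i in seq_len(n)) {
    v <- sort(x[i, !is.na(x[i, ])])
    if (length(v) == m_full) {
      ref_acc <- ref_acc + v
    } else {
      pts <- if (length(v) == 1) 0.5 else (seq_along(v) - 1) / (length(v) - 1)
      ref_acc <- ref_acc + stats::approx(pts, v, xout = grid, rule = 2)$y
    }
  }
  ref <- ref_acc / n
  res <- x
  for (i in seq_len(n)) {
    obs <- which(!is.na(x[i, ]))
    v <- x[i, obs]
    rk <- rank(v, ties.method = "average")
    if (length(v) == m_full) {
      # map (possibly fractional, for ties) ranks onto the reference
      res[i, obs] <- stats::approx(seq_len(m_full), ref, xout = rk, rule = 2)$y
    } else {
      pts <- if (length(v) == 1) 0.5 else (rk - 1) / (length(v) - 1)
      res[i, obs] <- stats::approx(grid, ref, xout = pts, rule = 2)$y
    }
  }
  res
}

#' Log2 transform with offset
#'
#' \code{v -> log2(v + offset)}; values at or below \code{-offset} are an
#' error.
#'
#' @param expr_matrix an expression \code{\link{probe_matrix}} or numeric
#'   matrix of raw signals.
#' @param offset additive offset (default 16).
#' @return object of the same type with transformed values.
#' @export
log2_offset_transform <- function(expr_matrix, offset = 16) {
  vals <- if (inherits(expr_matrix, "probe_matrix")) expr_matrix$values else expr_matrix
  if (any(vals <= -offset, na.rm = TRUE)) {
    stop("values <= -", offset, " cannot be log2 transformed")
  }
  tv <- log2(vals + offset)
  if (inherits(expr_matrix, "probe_matrix")) {
    probe_matrix(expr_matrix$samples, expr_matrix$probes, tv, "log2_expression")
  } else {
    tv
  }
}

#' Principal components of array control probes
#'
#' Column-centred PCA of a complete samples x control-probes intensity
#' matrix; the leading scores are used downstream as technical-bias
#' covariates.
#'
#' @param control_matrix samples x control-probes numeric matrix.
#' @param n_pcs number of components (default 6).
#' @return data.frame of scores (columns \code{ctrlPC1..}) with attribute
#'   \code{"variance_proportion"}.
#' @export
control_probe_pcs <- function(control_matrix, n_pcs = 6) {
  if (anyNA(control_matrix)) stop("control matrix must be complete")
  if (nrow(control_matrix) < n_pcs) stop("fewer samples than requested PCs")
  if (n_pcs > min(dim(control_matrix))) stop("n_pcs exceeds matrix rank bound")
  pcs <- centered_pca(control_matrix, n_pcs)
  colnames(pcs$scores) <- paste0("ctrlPC", seq_len(n_pcs))
  out <- as.data.frame(pcs$scores)
  rownames(out) <- rownames(control_matrix)
  attr(out, "variance_proportion") <- pcs$varprop[seq_len(n_pcs)]
  out
}

# shared centered-PCA core (scores = U d); varprop over all components
centered_pca <- function(x, n_pcs) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc, nu = n_pcs, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  list(scores = scores, varprop = sv$d^2 / sum(sv$d^2))
}
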