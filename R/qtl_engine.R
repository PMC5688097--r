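# The cis-QTL engine: cis-pair enumeration, covariate assembly (genotype
# PCs, confounder residuals, hidden-confounder PCs), the additive linear
# model, joint Benjamini-Hochberg FDR, per-covariate variance
# decomposition, and the vectorized scan driver.
#
# The scan uses the Frisch-Waugh identity: phenotypes and dosages are
# residualized on [intercept + covariates] once, after which the per-pair
# t statistic of the dosage term is a function of the residual
# correlation. This is algebraically identical to refitting the full OLS
# model per pair (asserted in the test suite) and is what makes scans of
# 10^5 pairs fast.

#' Scan configuration
#'
#' @param window_bp cis-window half-width in bp; a SNP-probe pair is
#'   tested iff same chromosome and distance <= window (boundary
#'   inclusive).
#' @param fdr_level Benjamini-Hochberg level applied jointly over all
#'   tested pairs of the scan.
#' @param decompose which records receive the per-covariate variance
#'   decomposition: significant ones (default), all, or none.
#' @return list of class \code{scan_config}.
#' @export
scan_config <- function(window_bp = 500000, fdr_level = 0.01,
                        decompose = c("significant", "all", "none")) {
  if (window_bp <= 0) stop("window_bp must be positive")
  if (fdr_level <= 0 || fdr_level >= 1) stop("fdr_level must lie in (0, 1)")
  structure(list(window_bp = window_bp, fdr_level = fdr_level,
                 decompose = match.arg(decompose)),
            class = "scan_config")
}

#' Enumerate cis SNP-probe pairs
#'
#' Sorted sweep per chromosome (no all-pairs scan): for every probe, the
#' SNPs whose position lies within \code{window_bp} of the probe anchor
#' are located by binary search on the position-sorted SNP vector.
#'
#' @param snp_ann SNP annotation data.frame (snp_id, chrom, pos).
#' @param probe_ann probe annotation data.frame (probe_id, chrom,
#'   anchor_pos).
#' @param window_bp inclusive window half-width.
#' @return data.frame (snp_idx, probe_idx, snp_id, probe_id, distance_bp)
#'   with indices into the input annotation rows.
#' @export
enumerate_cis_pairs <- function(snp_ann, probe_ann, window_bp = 500000) {
  res <- vector("list", 0)
  for (ch in intersect(unique(probe_ann$chrom), unique(snp_ann$chrom))) {
    si <- which(snp_ann$chrom == ch)
    si <- si[order(snp_ann$pos[si])]
    sp <- snp_ann$pos[si]
    pi <- which(probe_ann$chrom == ch)
    lo <- findInterval(probe_ann$anchor_pos[pi] - window_bp, sp,
                       left.open = TRUE) + 1L
    hi <- findInterval(probe_ann$anchor_pos[pi] + window_bp, sp)
    n_each <- pmax(hi - lo + 1L, 0L)
    keep <- n_each > 0L
    if (!any(keep)) next
    probe_idx <- rep(pi[keep], n_each[keep])
    snp_pos_in_sorted <- unlist(Map(seq, lo[keep], hi[keep]))
    snp_idx <- si[snp_pos_in_sorted]
    res[[length(res) + 1]] <- data.frame(
      snp_idx = snp_idx, probe_idx = probe_idx,
      snp_id = snp_ann$snp_id[snp_idx],
      probe_id = probe_ann$probe_id[probe_idx],
      distance_bp = abs(snp_ann$pos[snp_idx] - probe_ann$anchor_pos[probe_idx]),
      stringsAsFactors = FALSE)
  }
  if (!length(res)) {
    return(data.frame(snp_idx = integer(0), probe_idx = integer(0),
                      snp_id = character(0), probe_id = character(0),
                      distance_bp = numeric(0)))
  }
  do.call(rbind, res)
}

#' Genotype principal components for population-stratification control
#'
#' PCA of the samples x SNPs dosage matrix with each column centred at
#' \eqn{2p} and scaled by \eqn{\sqrt{2p(1-p)}} (allele-frequency
#' standardization), as used for ethnicity adjustment in association
#' scans.
#'
#' @param genotypes a \code{\link{genotype_matrix}}.
#' @param n_pcs number of components (default 3).
#' @return data.frame of scores (columns \code{genoPC1..}) with a
#'   \code{"variance_proportion"} attribute.
#' @export
compute_genotype_pcs <- function(genotypes, n_pcs = 3) {
  d <- imputed_dosage(genotypes)
  p <- colMeans(d) / 2
  ok <- p > 0 & p < 1
  if (sum(ok) < n_pcs) stop("too few polymorphic SNPs for the requested PCs")
  x <- sweep(d[, ok, drop = FALSE], 2, 2 * p[ok], "-")
  x <- sweep(x, 2, sqrt(2 * p[ok] * (1 - p[ok])), "/")
  sv <- svd(x, nu = n_pcs, nv = 0)
  if (sv$d[n_pcs] < 1e-12) stop("degenerate genotype matrix")
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  colnames(scores) <- paste0("genoPC", seq_len(n_pcs))
  out <- as.data.frame(scores)
  rownames(out) <- genotypes$samples
  attr(out, "variance_proportion") <- (sv$d^2 / sum(sv$d^2))[seq_len(n_pcs)]
  out
}

# design matrix [1 | covariates] with rank check
covariate_design <- function(covariates, n) {
  if (is.null(covariates) || (!is.null(ncol(covariates)) && ncol(covariates) == 0)) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  X
}

#' Residualize a matrix over covariates
#'
#' Per probe, subtracts the least-squares projection on
#' \code{[intercept + covariates]}.
#'
#' @param mat a \code{\link{probe_matrix}} or samples x probes matrix.
#' @param covariates data.frame/matrix of covariates (complete; full
#'   rank, or an error names the collinear columns).
#' @return same type as the input; probe matrices come back with
#'   \code{value_kind = "residual"}.
#' @export
residualize <- function(mat, covariates) {
  vals <- if (inherits(mat, "probe_matrix")) mat$values else as.matrix(mat)
  if (anyNA(covariates)) stop("covariates contain missing values")
  X <- covariate_design(covariates, nrow(vals))
  res <- stats::lm.fit(X, vals)$residuals
  res <- as.matrix(res)
  dimnames(res) <- dimnames(vals)
  if (inherits(mat, "probe_matrix")) {
    probe_matrix(mat$samples, mat$probes, res, "residual")
  } else {
    res
  }
}

#' Hidden-confounder principal components
#'
#' Centred PCA of a samples x probes residual matrix; the leading scores
#' are used as unknown-confounder covariates in the scan.
#'
#' @param residual_matrix residual \code{\link{probe_matrix}} or matrix.
#' @param n_pcs number of components.
#' @return data.frame of scores (columns \code{hiddenPC1..}) with a
#'   \code{"variance_proportion"} attribute.
#' @export
hidden_confounder_pcs <- function(residual_matrix, n_pcs) {
  vals <- if (inherits(residual_matrix, "probe_matrix")) {
    residual_matrix$values
  } else {
    as.matrix(residual_matrix)
  }
  if (anyNA(vals)) stop("residual matrix must be complete")
  if (n_pcs > min(dim(vals)) - 1) stop("n_pcs exceeds the matrix rank")
  pcs <- centered_pca(vals, n_pcs)
  colnames(pcs$scores) <- paste0("hiddenPC", seq_len(n_pcs))
  out <- as.data.frame(pcs$scores)
  rownames(out) <- rownames(vals)
  attr(out, "variance_proportion") <- pcs$varprop[seq_len(n_pcs)]
  out
}

#' Fit the additive single-SNP linear model
#'
#' Ordinary least squares of \code{y} on
#' \code{[intercept, dosage, covariates]}; the dosage coefficient is the
#' per-alt-allele effect, with a t test on \code{n - k} residual degrees
#' of freedom. Missing dosages are mean-imputed; a monomorphic dosage
#' yields \code{NULL} (the scan logs and skips such records).
#'
#' @param y numeric response vector.
#' @param dosage numeric dosage vector.
#' @param covariate_matrix optional covariate data.frame/matrix.
#' @return list (beta, se, t, p, df) or NULL for monomorphic dosage.
#' @export
fit_additive_model <- function(y, dosage, covariate_matrix = NULL) {
  g <- dosage
  g[is.na(g)] <- mean(g, na.rm = TRUE)
  if (stats::sd(g) == 0) {
    message("monomorphic dosage: record skipped")
    return(NULL)
  }
  C <- covariate_design(covariate_matrix, length(y))
  X <- cbind(C[, 1, drop = FALSE], dosage = g, C[, -1, drop = FALSE])
  n <- length(y)
  k <- ncol(X)
  if (n <= k + 1) stop("too few samples for the model")
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - k)
  XtXinv <- chol2inv(qr.R(fit$qr))
  # dosage is the 2nd column of X but lm.fit may have pivoted
  j <- which(fit$qr$pivot == 2)
  beta <- unname(fit$coefficients["dosage"])
  se <- sqrt(sigma2 * XtXinv[j, j])
  t <- beta / se
  list(beta = beta, se = se, t = t,
       p = 2 * stats::pt(-abs(t), df = n - k), df = n - k)
}

#' Benjamini-Hochberg FDR flags and data-dependent p threshold
#'
#' Step-up procedure applied jointly over all supplied p-values (all cis
#' pairs of a scan). Returns the rejection flags and the largest rejected
#' p-value — the scan's data-dependent significance threshold.
#'
#' @param p_values numeric vector in (0, 1].
#' @param level FDR level (default 0.01).
#' @return list(significant = logical vector, p_threshold = numeric or NA).
#' @export
bh_fdr <- function(p_values, level = 0.01) {
  if (!length(p_values)) {
    return(list(significant = logical(0), p_threshold = NA_real_))
  }
  flags <- stats::p.adjust(p_values, method = "BH") <= level
  list(significant = flags,
       p_threshold = if (any(flags)) max(p_values[flags]) else NA_real_)
}

#' Per-term variance decomposition by leave-one-term-out refits
#'
#' For each term T, the share is R-squared(full model) minus
#' R-squared(model without T), clipped at zero when non-orthogonality
#' makes the refit difference negative. The genotype share is computed the
#' same way.
#'
#' @param y response vector.
#' @param dosage dosage vector (mean-imputed internally).
#' @param covariates covariate data.frame/matrix.
#' @param terms named list mapping a term name to the covariate column
#'   names it groups; default: every covariate column is its own term.
#' @return named numeric vector of shares, first element \code{genotype}.
#' @export
variance_decomposition <- function(y, dosage, covariates = NULL, terms = NULL) {
  g <- dosage
  g[is.na(g)] <- mean(g, na.rm = TRUE)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  if (is.null(terms)) {
    terms <- if (is.null(C)) list() else as.list(stats::setNames(colnames(C), colnames(C)))
  }
  r2_of <- function(cols_dropped, drop_genotype = FALSE) {
    Xc <- if (is.null(C)) NULL else C[, setdiff(colnames(C), cols_dropped), drop = FALSE]
    X <- cbind(rep(1, length(y)), if (!drop_genotype) g, Xc)
    fit <- stats::lm.fit(X, y)
    tss <- sum((y - mean(y))^2)
    1 - sum(fit$residuals^2) / tss
  }
  full <- r2_of(character(0))
  shares <- c(genotype = max(0, full - r2_of(character(0), drop_genotype = TRUE)))
  for (nm in names(terms)) {
    shares[nm] <- max(0, full - r2_of(terms[[nm]]))
  }
  shares
}

#' Run a cis-QTL scan
#'
#' Fits every cis SNP-probe pair with the additive model and the supplied
#' covariates, applies Benjamini-Hochberg FDR jointly across all pairs,
#' and (for significant records by default) decomposes the phenotype
#' variance into genotype / neuronal / age / gender shares.
#'
#' @param genotypes a \code{\link{genotype_matrix}}.
#' @param probe_mat a \code{\link{probe_matrix}} aligned to the same
#'   samples.
#' @param covariates complete covariate data.frame (rownames = sample
#'   ids) — known confounders plus any PC columns; may be NULL.
#' @param config a \code{\link{scan_config}}.
#' @param variance_terms named list passed to
#'   \code{\link{variance_decomposition}}; defaults to the columns named
#'   \code{neuronal_proportion}, \code{age_years}, \code{gender} when
#'   present.
#' @return list of class \code{cis_scan}: \code{records} (one row per
#'   tested pair: snp_id, probe_id, snp_pos, distance_bp, beta, se, t, p,
#'   fdr_significant, r2_genotype, r2_neuronal, r2_age, r2_gender) and
#'   \code{summary} (tested/significant pair and probe counts, p
#'   threshold, median |beta| and median distance over each significant
#'   probe's top pair).
#' @export
run_cis_scan <- function(genotypes, probe_mat, covariates = NULL,
                         config = scan_config(), variance_terms = NULL) {
  if (!identical(genotypes$samples, probe_mat$samples)) {
    stop("sample misalignment between genotypes and probe matrix")
  }
  if (!is.null(covariates) && !identical(rownames(covariates), genotypes$samples)) {
    stop("sample misalignment between genotypes and covariates")
  }
  pairs <- enumerate_cis_pairs(genotypes$snps, probe_mat$probes,
                               config$window_bp)
  n <- length(genotypes$samples)
  X <- covariate_design(covariates, n)
  k_cov <- ncol(X) - 1
  df <- n - k_cov - 2
  if (df < 1) stop("too few samples for the covariate design")
  G <- imputed_dosage(genotypes)
  poly <- apply(G, 2, stats::sd) > 0
  n_skipped <- sum(pairs$snp_idx %in% which(!poly))
  if (n_skipped) {
    message(n_skipped, " pair(s) skipped: monomorphic dosage")
    pairs <- pairs[poly[pairs$snp_idx], , drop = FALSE]
  }
  Y <- probe_mat$values
  Gres <- as.matrix(stats::lm.fit(X, G)$residuals)
  Yres <- as.matrix(stats::lm.fit(X, Y)$residuals)
  gn <- sqrt(colSums(Gres^2))
  yn <- sqrt(colSums(Yres^2))
  # residual correlation per pair, from the full cross-product per chromosome
  r <- numeric(nrow(pairs))
  if (nrow(pairs)) {
    R <- crossprod(Gres, Yres) / outer(gn, yn)
    r <- R[cbind(pairs$snp_idx, pairs$probe_idx)]
  }
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt(df / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = df)
  beta <- r * yn[pairs$probe_idx] / gn[pairs$snp_idx]
  se <- yn[pairs$probe_idx] * sqrt((1 - r^2) / df) / gn[pairs$snp_idx]
  fdr <- bh_fdr(p, config$fdr_level)
  records <- data.frame(
    snp_id = pairs$snp_id, probe_id = pairs$probe_id,
    snp_pos = genotypes$snps$pos[pairs$snp_idx],
    distance_bp = pairs$distance_bp,
    beta = beta, se = se, t = tstat, p = p,
    fdr_significant = fdr$significant,
    r2_genotype = NA_real_, r2_neuronal = NA_real_,
    r2_age = NA_real_, r2_gender = NA_real_,
    stringsAsFactors = FALSE)
  # per-covariate variance shares, by leave-one-term-out refits
  if (config$decompose != "none" && nrow(records)) {
    todo <- if (config$decompose == "all") seq_len(nrow(records)) else which(fdr$significant)
    if (is.null(variance_terms)) {
      known <- intersect(c("neuronal_proportion", "age_years", "gender"),
                         colnames(covariates))
      variance_terms <- as.list(stats::setNames(known, known))
    }
    field_of <- c(neuronal_proportion = "r2_neuronal", age_years = "r2_age",
                  gender = "r2_gender")
    for (i in todo) {
      sh <- variance_decomposition(Y[, pairs$probe_idx[i]],
                                   G[, pairs$snp_idx[i]],
                                   covariates, variance_terms)
      records$r2_genotype[i] <- min(sh[["genotype"]], 1)
      for (nm in names(variance_terms)) {
        fld <- field_of[nm]
        if (!is.na(fld)) records[[fld]][i] <- min(sh[[nm]], 1)
      }
    }
  }
  sig <- records[records$fdr_significant, , drop = FALSE]
  top <- if (nrow(sig)) {
    sig <- sig[order(sig$probe_id, sig$p, sig$snp_pos), ]
    sig[!duplicated(sig$probe_id), ]
  } else {
    sig
  }
  summary <- list(
    n_pairs_tested = nrow(records),
    n_significant_pairs = sum(records$fdr_significant),
    n_significant_probes = length(unique(sig$probe_id)),
    p_threshold = fdr$p_threshold,
    fdr_level = config$fdr_level,
    median_abs_beta_top = if (nrow(top)) stats::median(abs(top$beta)) else NA_real_,
    median_distance_top = if (nrow(top)) stats::median(top$distance_bp) else NA_real_)
  structure(list(records = records, summary = summary, config = config),
            class = "cis_scan")
}

#' @export
print.cis_scan <- function(x, ...) {
  s <- x$summary
  cat(sprintf("cis scan: %d pairs tested, %d significant (%d probes) at FDR %.2g\n",
              s$n_pairs_tested, s$n_significant_pairs, s$n_significant_probes,
              s$fdr_level))
  if (!is.na(s$p_threshold)) {
    cat(sprintf("  p threshold %.3g; top-pair median |beta| %.4g, median distance %.0f bp\n",
                s$p_threshold, s$median_abs_beta_top, s$median_distance_top))
  }
  invisible(x)
}
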