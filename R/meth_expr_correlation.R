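# Cis correlation of CpG methylation with transcript expression on
# confounder residuals, detection of shared genetic drivers behind
# coincident meQTL/eQTL pairs, and the promoter-direction summary.

#' Cis methylation-expression correlation
#'
#' Pearson correlation between CpG residuals and expression residuals for
#' every cis pair, with the window anchored on the expression probe
#' (5'-TSS); two-sided p from the t transform and Benjamini-Hochberg
#' flags over all tested pairs. Pairs with a zero-variance residual
#' vector are skipped with a log message.
#'
#' @param meth_residuals residual \code{\link{probe_matrix}} of CpGs.
#' @param expr_residuals residual \code{\link{probe_matrix}} of
#'   transcripts, same samples.
#' @param window_bp window half-width around the expression anchor
#'   (inclusive; default 500 kb).
#' @param fdr FDR level (default 0.01).
#' @return data.frame with one row per tested pair: cpg_id,
#'   expr_probe_id, cpg_chrom, cpg_pos, distance_bp, pearson_r,
#'   r_squared, p_value, fdr_significant, direction.
#' @export
correlate_cis <- function(meth_residuals, expr_residuals,
                          window_bp = 500000, fdr = 0.01) {
  if (!identical(meth_residuals$samples, expr_residuals$samples)) {
    stop("sample misalignment between methylation and expression residuals")
  }
  # role reversal of the QTL pairing: "snp" slot = CpG, window anchored
  # on the expression probe
  pairs <- enumerate_cis_pairs(
    data.frame(snp_id = meth_residuals$probes$probe_id,
               chrom = meth_residuals$probes$chrom,
               pos = meth_residuals$probes$anchor_pos,
               stringsAsFactors = FALSE),
    expr_residuals$probes, window_bp)
  M <- meth_residuals$values
  E <- expr_residuals$values
  n <- nrow(M)
  ok_m <- apply(M, 2, stats::sd) > 0
  ok_e <- apply(E, 2, stats::sd) > 0
  drop <- !(ok_m[pairs$snp_idx] & ok_e[pairs$probe_idx])
  if (any(drop)) {
    message(sum(drop), " pair(s) skipped: zero-variance residual vector")
    pairs <- pairs[!drop, , drop = FALSE]
  }
  Ms <- scale(M)
  Es <- scale(E)
  r <- numeric(nrow(pairs))
  if (nrow(pairs)) {
    R <- crossprod(Ms, Es) / (n - 1)
    r <- pmin(pmax(R[cbind(pairs$snp_idx, pairs$probe_idx)], -1), 1)
  }
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  flags <- bh_fdr(p, fdr)$significant
  data.frame(cpg_id = pairs$snp_id,
             expr_probe_id = pairs$probe_id,
             cpg_chrom = meth_residuals$probes$chrom[pairs$snp_idx],
             cpg_pos = meth_residuals$probes$anchor_pos[pairs$snp_idx],
             distance_bp = pairs$distance_bp,
             pearson_r = r, r_squared = r^2, p_value = p,
             fdr_significant = flags,
             direction = sign(r),
             stringsAsFactors = FALSE)
}

# top SNP per probe: smallest p, ties broken by smaller position
top_snp_per_probe <- function(records) {
  rec <- records[order(records$probe_id, records$p, records$snp_pos), ]
  rec[!duplicated(rec$probe_id), c("probe_id", "snp_id")]
}

#' Shared genetic drivers of correlated CpG-transcript pairs
#'
#' For every significant methylation-expression correlation whose CpG is
#' a meQTL and whose transcript is an eQTL, computes the LD between the
#' two probes' top SNPs and emits the pair when r-squared reaches
#' \code{r2_min} — evidence that one SNP (or a tight LD pair) drives both
#' molecular traits.
#'
#' @param meqtl_records,eqtl_records scan record data.frames (columns
#'   snp_id, probe_id, snp_pos, p, fdr_significant).
#' @param correlation_records output of \code{\link{correlate_cis}}.
#' @param genotypes a \code{\link{genotype_matrix}} covering the top
#'   SNPs.
#' @param r2_min LD threshold (default 0.4).
#' @return data.frame (cpg_id, expr_probe_id, meqtl_snp, eqtl_snp,
#'   r2_between_snps).
#' @export
find_shared_drivers <- function(meqtl_records, eqtl_records,
                                correlation_records, genotypes,
                                r2_min = 0.4) {
  sig_me <- meqtl_records[meqtl_records$fdr_significant, , drop = FALSE]
  sig_eq <- eqtl_records[eqtl_records$fdr_significant, , drop = FALSE]
  top_me <- top_snp_per_probe(sig_me)
  top_eq <- top_snp_per_probe(sig_eq)
  cand <- correlation_records[correlation_records$fdr_significant &
                                correlation_records$cpg_id %in% top_me$probe_id &
                                correlation_records$expr_probe_id %in% top_eq$probe_id,
                              , drop = FALSE]
  out <- data.frame(cpg_id = character(0), expr_probe_id = character(0),
                    meqtl_snp = character(0), eqtl_snp = character(0),
                    r2_between_snps = numeric(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cand))) {
    s1 <- top_me$snp_id[match(cand$cpg_id[i], top_me$probe_id)]
    s2 <- top_eq$snp_id[match(cand$expr_probe_id[i], top_eq$probe_id)]
    d1 <- genotypes$dosage[, s1]
    d2 <- genotypes$dosage[, s2]
    if (stats::sd(d1, na.rm = TRUE) == 0 || stats::sd(d2, na.rm = TRUE) == 0) next
    r2 <- ld_r2(d1, d2)
    if (r2 >= r2_min) {
      out <- rbind(out, data.frame(cpg_id = cand$cpg_id[i],
                                   expr_probe_id = cand$expr_probe_id[i],
                                   meqtl_snp = s1, eqtl_snp = s2,
                                   r2_between_snps = r2,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' Direction summary of methylation-expression correlations
#'
#' Counts positive and negative correlations overall and inside/outside a
#' promoter track, with a Fisher odds ratio for (negative direction x
#' promoter membership).
#'
#' @param correlation_records output of \code{\link{correlate_cis}}
#'   (significant rows are summarized).
#' @param promoter_track an \code{\link{interval_track}} of promoter
#'   regions; CpG positions are taken from the record columns.
#' @return list: n, n_negative, fraction_negative, table (2x2 counts),
#'   fisher (see \code{\link{fisher_enrichment}}).
#' @export
direction_summary <- function(correlation_records, promoter_track) {
  rec <- correlation_records[correlation_records$fdr_significant, , drop = FALSE]
  if (!nrow(rec)) {
    return(list(n = 0, n_negative = 0, fraction_negative = NA_real_,
                table = NULL, fisher = NULL))
  }
  in_prom <- overlap_flags(data.frame(chrom = rec$cpg_chrom, pos = rec$cpg_pos),
                           promoter_track)
  neg <- rec$direction < 0
  tab <- c(neg_in = sum(neg & in_prom), pos_in = sum(!neg & in_prom),
           neg_out = sum(neg & !in_prom), pos_out = sum(!neg & !in_prom))
  fis <- if (all(c(tab["neg_in"] + tab["pos_in"],
                   tab["neg_out"] + tab["pos_out"],
                   tab["neg_in"] + tab["neg_out"],
                   tab["pos_in"] + tab["pos_out"]) > 0)) {
    fisher_enrichment(tab[["neg_in"]], tab[["pos_in"]],
                      tab[["neg_out"]], tab[["pos_out"]])
  } else {
    NULL
  }
  list(n = nrow(rec), n_negative = sum(neg),
       fraction_negative = mean(neg), table = tab, fisher = fis)
}
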