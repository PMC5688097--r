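# Empirical LD-overlap enrichment of QTL-SNP sets against reference SNP
# sets (other QTL catalogs, GWAS hit lists): clump both sets to
# quasi-independent index SNPs, count LD overlaps, and compare the
# observed count with a null built from MAF-matched control sets.

#' Empirical enrichment record
#'
#' Arithmetic core shared by simulated and tabulated summaries:
#' enrichment = observed / null mean, error of the mean =
#' sd / sqrt(n_sets).
#'
#' @param observed observed overlap count.
#' @param null_mean,null_sd mean and sd of the null overlap counts.
#' @param n_sets number of null sets.
#' @param empirical_p fraction of null sets reaching the observed count
#'   (optional for tabulated summaries).
#' @param n_target,n_reference clumped set sizes (optional).
#' @return list of class \code{empirical_enrichment}.
#' @export
empirical_enrichment_record <- function(observed, null_mean, null_sd = NA_real_,
                                        n_sets = NA_integer_,
                                        empirical_p = NA_real_,
                                        n_target = NA_integer_,
                                        n_reference = NA_integer_) {
  enrichment <- if (!is.na(null_mean) && null_mean > 0) observed / null_mean else NA_real_
  if (is.na(enrichment)) warning("null mean is zero: enrichment undefined")
  structure(list(n_target_clumped = n_target,
                 n_reference_clumped = n_reference,
                 observed_overlap = observed,
                 null_mean = null_mean, null_sd = null_sd,
                 error_of_mean = null_sd / sqrt(n_sets),
                 enrichment = enrichment,
                 empirical_p = empirical_p, n_sets = n_sets),
            class = "empirical_enrichment")
}

#' @export
print.empirical_enrichment <- function(x, ...) {
  cat(sprintf("LD-overlap enrichment: observed %d vs null %.2f +/- %.2f -> %.2f-fold",
              x$observed_overlap, x$null_mean, x$null_sd, x$enrichment))
  if (!is.na(x$empirical_p)) {
    lab <- if (x$empirical_p == 0) sprintf("< %.2g", 1 / x$n_sets)
           else sprintf("= %.3g", x$empirical_p)
    cat(sprintf(" (empirical p %s)", lab))
  }
  cat("\n")
  invisible(x)
}

#' Count LD overlaps between two clumped SNP sets
#'
#' Number of SNPs in set A with at least one SNP in set B at r-squared >=
#' \code{r2_min} within \code{window_bp}. A SNP present in both sets
#' counts (r-squared with itself is 1).
#'
#' @param set_a,set_b character vectors of snp_ids.
#' @param genotypes a \code{\link{genotype_matrix}} covering both sets.
#' @param r2_min LD threshold (default 0.25).
#' @param window_bp inclusive pairwise distance limit.
#' @return integer count.
#' @export
count_ld_overlap <- function(set_a, set_b, genotypes, r2_min = 0.25,
                             window_bp = 250000) {
  ann <- genotypes$snps
  ia <- match(set_a, ann$snp_id)
  ib <- match(set_b, ann$snp_id)
  missing <- c(set_a[is.na(ia)], set_b[is.na(ib)])
  if (length(missing)) {
    stop("SNPs absent from genotypes: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  flags <- overlap_flags_vs_reference(ia, ib, genotypes, r2_min, window_bp)
  sum(flags)
}

# per-SNP overlap indicator of index set `ia` against reference indices
# `ib`; shared by count_ld_overlap and the null machinery (a set's
# overlap count is the sum of its members' indicators)
overlap_flags_vs_reference <- function(ia, ib, genotypes, r2_min, window_bp) {
  ann <- genotypes$snps
  d <- imputed_dosage(genotypes)
  flags <- logical(length(ia))
  ref_by_chrom <- split(ib, ann$chrom[ib])
  for (k in seq_along(ia)) {
    i <- ia[k]
    refs <- ref_by_chrom[[ann$chrom[i]]]
    if (is.null(refs)) next
    refs <- refs[abs(ann$pos[refs] - ann$pos[i]) <= window_bp]
    if (!length(refs)) next
    if (any(refs == i)) { flags[k] <- TRUE; next }
    if (stats::sd(d[, i]) == 0) next
    r2 <- suppressWarnings(stats::cor(d[, i], d[, refs, drop = FALSE]))^2
    flags[k] <- any(r2 >= r2_min, na.rm = TRUE)
  }
  flags
}

#' Empirical LD-overlap enrichment against MAF-matched null sets
#'
#' Draws \code{n_sets} MAF-matched control sets from the pool, counts
#' each set's LD overlap with the reference set, and summarizes the
#' observed count against the resulting null. The empirical p is the
#' fraction of null sets reaching or exceeding the observed count
#' (reported as \code{< 1/n_sets} when that fraction is zero); the
#' add-one rule (k+1)/(n+1) is available via \code{p_rule}.
#'
#' @param observed observed overlap count of the target set.
#' @param target_set data.frame (snp_id, maf) of the clumped target SNPs.
#' @param control_pool data.frame (snp_id, maf) of clumped non-QTL
#'   control SNPs, disjoint from the targets.
#' @param reference_set character vector of clumped reference snp_ids.
#' @param genotypes a \code{\link{genotype_matrix}}.
#' @param n_sets number of null sets (>= 100).
#' @param r2_min,window_bp overlap LD threshold and window.
#' @param maf_bin_width MAF bin width for matching (default 0.02).
#' @param seed RNG seed.
#' @param p_rule \code{"k_over_n"} (default) or \code{"plus_one"}.
#' @return an \code{\link{empirical_enrichment_record}} with the null
#'   counts attached as attribute \code{"null_counts"}.
#' @export
empirical_enrichment <- function(observed, target_set, control_pool,
                                 reference_set, genotypes, n_sets = 10000,
                                 r2_min = 0.25, window_bp = 250000,
                                 maf_bin_width = 0.02, seed = 1L,
                                 p_rule = c("k_over_n", "plus_one")) {
  p_rule <- match.arg(p_rule)
  if (n_sets < 100) stop("n_sets must be >= 100")
  ann <- genotypes$snps
  ib <- match(reference_set, ann$snp_id)
  ipool <- match(control_pool$snp_id, ann$snp_id)
  if (anyNA(ib) || anyNA(ipool)) stop("SNPs absent from genotypes")
  pool_flags <- overlap_flags_vs_reference(ipool, ib, genotypes, r2_min, window_bp)
  names(pool_flags) <- control_pool$snp_id
  sets <- maf_matched_sets(control_pool, target_set, n_sets, maf_bin_width, seed)
  null_counts <- vapply(sets, function(s) sum(pool_flags[s]), numeric(1))
  k <- sum(null_counts >= observed)
  emp_p <- switch(p_rule,
                  k_over_n = k / n_sets,
                  plus_one = (k + 1) / (n_sets + 1))
  rec <- empirical_enrichment_record(
    observed, mean(null_counts), stats::sd(null_counts), n_sets, emp_p,
    n_target = nrow(target_set), n_reference = length(reference_set))
  attr(rec, "null_counts") <- null_counts
  rec
}

#' Exclude SNPs in a genomic region
#'
#' Removes SNPs inside the 1-based inclusive interval
#' \code{[start, end]} on \code{chrom}; used to drop the extended-LD MHC
#' region before overlap counting.
#'
#' @param snps data.frame with \code{chrom} and \code{pos}.
#' @param chrom,start,end region coordinates.
#' @return filtered data.frame.
#' @export
exclude_region <- function(snps, chrom = "chr6", start = 2500000,
                           end = 3500000) {
  drop <- snps$chrom == chrom & snps$pos >= start & snps$pos <= end
  snps[!drop, , drop = FALSE]
}

#' End-to-end LD-overlap enrichment run
#'
#' Clumps the target QTL SNPs and the reference SNPs at
#' (\code{clump_r2}, \code{clump_window_bp}), excludes the configured
#' region from all sets, counts the LD overlap at (\code{overlap_r2},
#' \code{overlap_window_bp}), and builds the MAF-matched empirical null
#' from a clumped control pool of non-QTL SNPs.
#'
#' @param qtl_snp_stats data.frame (snp_id, p) of the target QTL SNPs.
#' @param reference_snp_list data.frame (snp_id, p) of reference SNPs
#'   (e.g. a GWAS hit list with \code{p = p_value}).
#' @param control_snp_stats data.frame (snp_id, p) of non-QTL control
#'   SNPs (the FDR > 10\% pool).
#' @param genotypes a \code{\link{genotype_matrix}}.
#' @param clump_r2,clump_window_bp clumping parameters (defaults 0.25,
#'   250 kb).
#' @param overlap_r2,overlap_window_bp overlap-counting parameters
#'   (defaults 0.25, 250 kb; 1 Mb is used for QTL-vs-QTL comparisons).
#' @param n_sets number of null sets.
#' @param exclude list(chrom, start, end) or NULL to skip region
#'   exclusion.
#' @param maf_bin_width,seed,p_rule passed to
#'   \code{\link{empirical_enrichment}}.
#' @return an \code{\link{empirical_enrichment_record}}.
#' @export
run_overlap_enrichment <- function(qtl_snp_stats, reference_snp_list,
                                   control_snp_stats, genotypes,
                                   clump_r2 = 0.25, clump_window_bp = 250000,
                                   overlap_r2 = 0.25,
                                   overlap_window_bp = 250000,
                                   n_sets = 10000,
                                   exclude = list(chrom = "chr6",
                                                  start = 2500000,
                                                  end = 3500000),
                                   maf_bin_width = 0.02, seed = 1L,
                                   p_rule = "k_over_n") {
  cl_target <- clump(qtl_snp_stats, genotypes, clump_r2, clump_window_bp)
  cl_ref <- clump(reference_snp_list, genotypes, clump_r2, clump_window_bp)
  cl_pool <- clump(control_snp_stats, genotypes, clump_r2, clump_window_bp)
  target <- cl_target$index_snps
  ref <- cl_ref$index_snps
  pool <- cl_pool$index_snps
  if (!is.null(exclude)) {
    target <- exclude_region(target, exclude$chrom, exclude$start, exclude$end)
    ref <- exclude_region(ref, exclude$chrom, exclude$start, exclude$end)
    pool <- exclude_region(pool, exclude$chrom, exclude$start, exclude$end)
  }
  pool <- pool[!(pool$snp_id %in% target$snp_id), , drop = FALSE]
  observed <- count_ld_overlap(target$snp_id, ref$snp_id, genotypes,
                               overlap_r2, overlap_window_bp)
  empirical_enrichment(observed,
                       target[, c("snp_id", "maf")],
                       pool[, c("snp_id", "maf")],
                       ref$snp_id, genotypes, n_sets,
                       overlap_r2, overlap_window_bp,
                       maf_bin_width, seed, p_rule)
}
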