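# Linkage-disequilibrium utilities: pairwise r2 on dosages, greedy
# pruning, p-value-ordered clumping, and MAF-matched control-set sampling.
# r2 is the squared Pearson correlation of (mean-imputed) dosage vectors —
# composite LD, matching what PLINK computes on unphased genotypes.

#' Pairwise LD (r-squared) between two dosage vectors
#'
#' @param dosage_a,dosage_b equal-length dosage vectors; missing values
#'   are mean-imputed before correlating.
#' @return squared Pearson correlation in \[0, 1\].
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  if (length(dosage_a) != length(dosage_b)) stop("dosage vectors differ in length")
  a <- dosage_a; a[is.na(a)] <- mean(a, na.rm = TRUE)
  b <- dosage_b; b[is.na(b)] <- mean(b, na.rm = TRUE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("LD undefined for a monomorphic dosage vector")
  }
  stats::cor(a, b)^2
}

# mean-imputed dosage matrix (samples x snps)
imputed_dosage <- function(genotypes) {
  d <- genotypes$dosage
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  d
}

#' Greedy LD pruning
#'
#' Left-to-right scan in position order per chromosome: a SNP is dropped
#' when its r-squared with any of the previous \code{window_snps} retained
#' SNPs reaches \code{r2_max}; otherwise it is retained. The fixed point
#' property holds: pruning the output again changes nothing.
#'
#' @param genotypes a \code{\link{genotype_matrix}} (position-sorted per
#'   chromosome).
#' @param r2_max drop threshold (default 0.8, i.e. keep pairs with
#'   r-squared < 0.8).
#' @param window_snps number of retained predecessors compared against.
#' @return character vector of kept snp_ids, input order preserved.
#' @export
ld_prune <- function(genotypes, r2_max = 0.8, window_snps = 50) {
  d <- imputed_dosage(genotypes)
  ann <- genotypes$snps
  kept <- character(0)
  for (ch in unique(ann$chrom)) {
    idx <- which(ann$chrom == ch)
    idx <- idx[order(ann$pos[idx])]
    kept_idx <- integer(0)
    for (j in idx) {
      window <- utils::tail(kept_idx, window_snps)
      drop <- FALSE
      if (length(window)) {
        sj <- stats::sd(d[, j])
        if (sj > 0) {
          r2 <- suppressWarnings(stats::cor(d[, j], d[, window, drop = FALSE]))^2
          drop <- any(r2 >= r2_max, na.rm = TRUE)
        }
      }
      if (!drop) kept_idx <- c(kept_idx, j)
    }
    kept <- c(kept, ann$snp_id[kept_idx])
  }
  kept[order(match(kept, ann$snp_id))]
}

#' P-value-ordered LD clumping
#'
#' Iteratively takes the most significant unassigned SNP as an index SNP
#' and absorbs every unassigned SNP within \code{window_bp} whose
#' r-squared with the index reaches \code{r2_min}. Ties on p are broken
#' by the smaller genomic position. Every input SNP ends up exactly once,
#' as an index or as a member.
#'
#' @param snp_pvalues data.frame with columns \code{snp_id} and \code{p}.
#' @param genotypes a \code{\link{genotype_matrix}} covering all SNPs.
#' @param r2_min clumping threshold (default 0.25).
#' @param window_bp maximal index-to-member distance in bp (inclusive).
#' @return list of class \code{clump_result}: \code{index_snps}
#'   (annotation rows ordered by ascending p), \code{members} (named list
#'   index snp_id -> member snp_ids), \code{r2_threshold},
#'   \code{window_bp}.
#' @export
clump <- function(snp_pvalues, genotypes, r2_min = 0.25, window_bp = 250000) {
  ann <- genotypes$snps
  sel <- match(snp_pvalues$snp_id, ann$snp_id)
  if (anyNA(sel)) {
    stop("SNPs absent from genotypes: ",
         paste(utils::head(snp_pvalues$snp_id[is.na(sel)], 5), collapse = ", "))
  }
  d <- imputed_dosage(genotypes)
  ord <- order(snp_pvalues$p, ann$pos[sel])
  pool <- ord  # positions into snp_pvalues, by ascending (p, pos)
  assigned <- rep(FALSE, nrow(snp_pvalues))
  index_rows <- integer(0)
  members <- list()
  for (k in pool) {
    if (assigned[k]) next
    assigned[k] <- TRUE
    index_rows <- c(index_rows, k)
    gi <- sel[k]
    cand <- which(!assigned &
                    ann$chrom[sel] == ann$chrom[gi] &
                    abs(ann$pos[sel] - ann$pos[gi]) <= window_bp)
    mem <- character(0)
    if (length(cand)) {
      r2 <- suppressWarnings(stats::cor(d[, gi], d[, sel[cand], drop = FALSE]))^2
      hit <- cand[!is.na(r2) & r2 >= r2_min]
      assigned[hit] <- TRUE
      mem <- snp_pvalues$snp_id[hit]
    }
    members[[snp_pvalues$snp_id[k]]] <- mem
  }
  idx_ann <- ann[sel[index_rows], , drop = FALSE]
  idx_ann$p <- snp_pvalues$p[index_rows]
  structure(list(index_snps = idx_ann, members = members,
                 r2_threshold = r2_min, window_bp = window_bp),
            class = "clump_result")
}

#' @export
print.clump_result <- function(x, ...) {
  cat(sprintf("clump_result: %d index SNPs over %d input SNPs (r2 >= %.2f, %d bp)\n",
              nrow(x$index_snps),
              nrow(x$index_snps) + sum(lengths(x$members)),
              x$r2_threshold, x$window_bp))
  invisible(x)
}

#' MAF-matched control SNP sets
#'
#' Draws \code{n_sets} sets from a control pool, each reproducing the
#' per-MAF-bin counts of the target set exactly. Sampling is without
#' replacement within a set and independent across sets.
#'
#' @param control_pool data.frame (snp_id, maf) of candidate controls,
#'   disjoint from the targets.
#' @param target_snps data.frame (snp_id, maf) of target SNPs.
#' @param n_sets number of sets.
#' @param maf_bin_width bin width over (0, 0.5\] (default 0.02).
#' @param seed RNG seed.
#' @return list of \code{n_sets} character vectors of snp_ids.
#' @export
maf_matched_sets <- function(control_pool, target_snps, n_sets,
                             maf_bin_width = 0.02, seed = 1L) {
  if (any(target_snps$snp_id %in% control_pool$snp_id)) {
    stop("control pool must be disjoint from the target set")
  }
  bin <- function(maf) pmin(ceiling(maf / maf_bin_width), ceiling(0.5 / maf_bin_width))
  tb <- bin(target_snps$maf)
  cb <- bin(control_pool$maf)
  need <- table(tb)
  pool_by_bin <- split(control_pool$snp_id, cb)
  for (b in names(need)) {
    avail <- length(pool_by_bin[[b]])
    if (avail < need[[b]]) {
      stop(sprintf("MAF bin %s: pool has %d SNPs but %d required",
                   b, avail, need[[b]]))
    }
  }
  local_seed(seed, {
    lapply(seq_len(n_sets), function(i) {
      unlist(lapply(names(need), function(b) {
        ids <- pool_by_bin[[b]]
        ids[sample.int(length(ids), need[[b]])]
      }), use.names = FALSE)
    })
  })
}
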