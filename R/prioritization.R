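# Epigenomic prioritization of QTL-SNPs: CADD-Phred thresholding with
# best-SNP-per-probe selection, CpG creation/abolition calls from the
# sequence context, TFBS-alteration joins, transcription-factor
# over-representation, and GWAS-catalog matching. External scores (CADD,
# TFBS predictions, GWAS catalogs) are consumed as plain TSV snapshots.

#' Filter QTL records by CADD-Phred score and mark the best SNP per probe
#'
#' Keeps records whose SNP scores strictly above \code{threshold} and
#' marks, for each probe, the record with the maximal score (ties broken
#' by smaller p, then smaller position). SNPs absent from the score table
#' are dropped with a log message.
#'
#' @param qtl_records data.frame with snp_id, probe_id, p, snp_pos.
#' @param cadd_table data.frame (snp_id, cadd_phred).
#' @param threshold CADD-Phred cutoff (strict >; default 5).
#' @return records with added \code{cadd_phred} and
#'   \code{is_best_for_probe} columns.
#' @export
filter_by_cadd <- function(qtl_records, cadd_table, threshold = 5) {
  score <- cadd_table$cadd_phred[match(qtl_records$snp_id, cadd_table$snp_id)]
  n_missing <- sum(is.na(score))
  if (n_missing) {
    message(n_missing, " record(s) dropped: SNP absent from CADD table")
  }
  keep <- !is.na(score) & score > threshold
  out <- qtl_records[keep, , drop = FALSE]
  out$cadd_phred <- score[keep]
  if (!nrow(out)) {
    out$is_best_for_probe <- logical(0)
    return(out)
  }
  ord <- order(out$probe_id, -out$cadd_phred, out$p, out$snp_pos)
  out <- out[ord, ]
  out$is_best_for_probe <- !duplicated(out$probe_id)
  out
}

#' CpG creation/abolition by an allele substitution
#'
#' Evaluates the presence of a CG dinucleotide on the forward strand in
#' (left base + allele) and (allele + right base) for the reference and
#' alternative alleles: present for ref and absent for alt is
#' \code{"abolishes"}, absent-to-present is \code{"creates"}, anything
#' else \code{"none"}. Callers supply the reverse-complemented context
#' for minus-strand analyses.
#'
#' @param ref_context_triplet 3-character string (left base, reference
#'   base, right base); the middle base must equal \code{ref_allele}.
#' @param ref_allele,alt_allele single bases in \{A, C, G, T\}.
#' @return one of \code{"creates"}, \code{"abolishes"}, \code{"none"}.
#' @export
cpg_disruption <- function(ref_context_triplet, ref_allele, alt_allele) {
  ctx <- toupper(ref_context_triplet)
  ref_allele <- toupper(ref_allele)
  alt_allele <- toupper(alt_allele)
  bases <- strsplit(ctx, "")[[1]]
  if (length(bases) != 3 || !all(c(bases, ref_allele, alt_allele) %in%
                                 c("A", "C", "G", "T"))) {
    stop("context and alleles must be A/C/G/T; context must have 3 bases")
  }
  if (bases[2] != ref_allele) stop("context middle base must equal ref_allele")
  has_cg <- function(allele) {
    paste0(bases[1], allele) == "CG" || paste0(allele, bases[3]) == "CG"
  }
  ref_cg <- has_cg(ref_allele)
  alt_cg <- has_cg(alt_allele)
  if (ref_cg && !alt_cg) "abolishes"
  else if (!ref_cg && alt_cg) "creates"
  else "none"
}

#' Join TFBS-alteration predictions onto SNP records
#'
#' Left join: every record keeps a (possibly empty) list of transcription
#' factors whose binding site the SNP is predicted to alter.
#'
#' @param snps data.frame with a \code{snp_id} column.
#' @param tfbs_table data.frame (snp_id, factor, delta_affinity).
#' @return input with added list-column \code{tfbs_hits} and integer
#'   \code{n_tfbs}.
#' @export
join_tfbs <- function(snps, tfbs_table) {
  by_snp <- split(tfbs_table$factor, tfbs_table$snp_id)
  hits <- by_snp[snps$snp_id]
  hits[vapply(hits, is.null, logical(1))] <- list(character(0))
  snps$tfbs_hits <- unname(hits)
  snps$n_tfbs <- lengths(snps$tfbs_hits)
  snps
}

#' Over-representation of one transcription factor among best SNPs
#'
#' Fisher 2x2 of (SNP has a predicted site of \code{factor}) against
#' (best set vs background set); reuses
#' \code{\link{fisher_enrichment}}.
#'
#' @param best_snps_tfbs,background_snps_tfbs outputs of
#'   \code{\link{join_tfbs}} for the two sets.
#' @param factor transcription-factor name.
#' @return list as returned by \code{\link{fisher_enrichment}}.
#' @export
tf_overrepresentation <- function(best_snps_tfbs, background_snps_tfbs,
                                  factor) {
  if (!nrow(background_snps_tfbs)) stop("empty background set")
  has <- function(tab) {
    vapply(tab$tfbs_hits, function(h) factor %in% h, logical(1))
  }
  hb <- has(best_snps_tfbs)
  hg <- has(background_snps_tfbs)
  fisher_enrichment(sum(hb), sum(!hb), sum(hg), sum(!hg))
}

#' Match SNPs against a GWAS catalog
#'
#' Exact snp_id matches with catalog p strictly below \code{p_max}.
#'
#' @param snps data.frame with \code{snp_id}.
#' @param catalog data.frame (snp_id, trait, p).
#' @param p_max significance cutoff (default 5e-8, strict <).
#' @return data.frame (snp_id, trait, p) of matches.
#' @export
match_gwas_catalog <- function(snps, catalog, p_max = 5e-8) {
  hit <- catalog[catalog$snp_id %in% snps$snp_id & catalog$p < p_max,
                 c("snp_id", "trait", "p"), drop = FALSE]
  rownames(hit) <- NULL
  hit
}
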