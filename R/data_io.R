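# Domain containers and file formats shared by all pipeline stages.
#
# Coordinate conventions, applied package-wide:
#   * SNP and probe positions are 1-based (VCF convention).
#   * Interval tracks are stored 0-based half-open (BED convention);
#     conversion to 1-based happens only where a point position is
#     tested against a track.

#' Construct a genotype matrix
#'
#' Bundles an additive-dosage matrix (samples x SNPs, values in \[0, 2\])
#' with its per-SNP annotation. The minor allele frequency is computed
#' from each dosage column and stored in the annotation; a pre-existing
#' \code{maf} column is checked against the recomputed value.
#'
#' @param samples character vector of unique sample identifiers.
#' @param snps data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos} (1-based bp), \code{ref_allele}, \code{alt_allele}.
#' @param dosage numeric matrix, \code{length(samples)} rows and
#'   \code{nrow(snps)} columns; \code{NA} encodes missing calls.
#' @return An object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(samples, snps, dosage) {
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  if (anyDuplicated(snps$snp_id)) stop("duplicate snp_id in annotation")
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != length(samples) || ncol(dosage) != nrow(snps)) {
    stop("dosage dimensions inconsistent with samples/snps")
  }
  if (any(snps$pos < 1)) stop("SNP positions must be >= 1")
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  maf <- apply(dosage, 2, maf_from_dosage)
  if (!is.null(snps$maf)) {
    bad <- which(abs(snps$maf - maf) > 1e-9 & !is.na(snps$maf))
    if (length(bad)) {
      stop("stored maf disagrees with dosage-derived maf for: ",
           paste(utils::head(snps$snp_id[bad], 5), collapse = ", "))
    }
  }
  snps$maf <- maf
  dimnames(dosage) <- list(samples, snps$snp_id)
  structure(list(samples = samples, snps = snps, dosage = dosage),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (MAF %.3f-%.3f)\n",
              length(x$samples), nrow(x$snps),
              min(x$snps$maf), max(x$snps$maf)))
  invisible(x)
}

#' Minor allele frequency of a dosage column
#'
#' @param d numeric vector of additive dosages in \[0, 2\]; \code{NA} ignored.
#' @return MAF in \[0, 0.5\].
#' @export
maf_from_dosage <- function(d) {
  af <- mean(d, na.rm = TRUE) / 2
  min(af, 1 - af)
}

#' Construct a probe matrix
#'
#' @param samples character vector of sample ids.
#' @param probes data.frame with \code{probe_id}, \code{chrom},
#'   \code{anchor_pos} (CpG coordinate for methylation probes, 5'-TSS for
#'   expression probes) and optionally \code{gene_symbol}.
#' @param values numeric matrix, samples x probes.
#' @param value_kind one of \code{"beta"}, \code{"mvalue"},
#'   \code{"log2_expression"}, \code{"residual"}. Beta values are
#'   validated to lie in \[0, 1\].
#' @return An object of class \code{probe_matrix}.
#' @export
probe_matrix <- function(samples, probes, values,
                         value_kind = c("beta", "mvalue",
                                        "log2_expression", "residual")) {
  value_kind <- match.arg(value_kind)
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  if (anyDuplicated(probes$probe_id)) stop("duplicate probe_id")
  if (any(probes$anchor_pos < 1)) stop("probe anchor positions must be >= 1")
  values <- as.matrix(values)
  if (nrow(values) != length(samples) || ncol(values) != nrow(probes)) {
    stop("value dimensions inconsistent with samples/probes")
  }
  if (value_kind == "beta") {
    v <- values[!is.na(values)]
    if (length(v) && (min(v) < 0 || max(v) > 1)) {
      stop("beta values outside [0, 1]")
    }
  }
  if (is.null(probes$gene_symbol)) probes$gene_symbol <- NA_character_
  dimnames(values) <- list(samples, probes$probe_id)
  structure(list(samples = samples, probes = probes, values = values,
                 value_kind = value_kind),
            class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat(sprintf("probe_matrix (%s): %d samples x %d probes\n",
              x$value_kind, length(x$samples), nrow(x$probes)))
  invisible(x)
}

#' Construct an interval track
#'
#' Intervals are stored 0-based half-open as in BED files. Intervals may
#' overlap; no merging is performed.
#'
#' @param name track name.
#' @param intervals data.frame with \code{chrom}, \code{start}, \code{end}.
#' @return An object of class \code{interval_track}.
#' @export
interval_track <- function(name, intervals) {
  if (nrow(intervals) && any(intervals$start >= intervals$end)) {
    stop("interval with start >= end in track ", name)
  }
  structure(list(name = name,
                 intervals = intervals[, c("chrom", "start", "end")]),
            class = "interval_track")
}

# GRanges view of a track (1-based inclusive), for overlap queries.
track_granges <- function(track) {
  iv <- track$intervals
  GenomicRanges::GRanges(
    seqnames = iv$chrom,
    ranges = IRanges::IRanges(start = iv$start + 1L, end = iv$end))
}

#' Read genotypes from VCF or dosage TSV
#'
#' The dosage TSV dialect is fixed: one row per SNP, tab-separated, columns
#' \code{snp_id chrom pos ref_allele alt_allele} followed by one column per
#' sample (header row carries sample ids), \code{NA} for missing. VCF input
#' uses the \code{DS} FORMAT field when present and \code{GT} otherwise;
#' multiallelic records are rejected.
#'
#' @param path input file.
#' @param format \code{"vcf"} or \code{"dosage_tsv"}.
#' @return A \code{\link{genotype_matrix}}.
#' @export
read_genotypes <- function(path, format = c("dosage_tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) stop("VCF contains no records: ", path)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    stop("multiallelic VCF record(s) not supported: ",
         paste(utils::head(fix$ID[multi], 5), collapse = ", "))
  }
  fmt <- v@gt[, 1]
  has_ds <- all(grepl("(^|:)DS(:|$)", fmt))
  if (has_ds) {
    dm <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    dm <- apply(gt, c(1, 2), gt_to_dosage)
  }
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  if (anyDuplicated(ids)) stop("duplicate snp_id in VCF")
  snps <- data.frame(snp_id = ids, chrom = fix$CHROM,
                     pos = as.integer(fix$POS),
                     ref_allele = fix$REF, alt_allele = fix$ALT,
                     stringsAsFactors = FALSE)
  genotype_matrix(colnames(dm), snps, t(dm))
}

gt_to_dosage <- function(g) {
  if (is.na(g)) return(NA_real_)
  alleles <- strsplit(sub(":.*$", "", g), "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_real_)
  sum(as.integer(alleles))
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "ref_allele", "alt_allele")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("dosage TSV missing columns: ", paste(miss, collapse = ", "))
  ann_cols <- c(need, intersect(c("maf", "block"), names(tab)))
  sample_cols <- setdiff(names(tab), ann_cols)
  if (!length(sample_cols)) stop("dosage TSV has no sample columns")
  dm <- as.matrix(tab[, sample_cols, drop = FALSE])
  if (!is.numeric(dm)) {
    bad <- which(apply(tab[, sample_cols, drop = FALSE], 1,
                       function(r) any(is.na(suppressWarnings(as.numeric(r))) & r != "NA")))[1]
    stop("unparseable dosage at data line ", bad, " of ", path)
  }
  snps <- tab[, setdiff(ann_cols, "maf")]
  genotype_matrix(sample_cols, snps, t(dm))
}

#' Write genotypes as dosage TSV
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param path output file.
#' @param provenance optional named list written as \code{#}-prefixed
#'   header lines.
#' @export
write_dosage_tsv <- function(geno, path, provenance = NULL) {
  ann_cols <- c("snp_id", "chrom", "pos", "ref_allele", "alt_allele",
                intersect("block", names(geno$snps)))
  tab <- cbind(geno$snps[, ann_cols], as.data.frame(t(geno$dosage)))
  write_tsv_with_header(tab, path, provenance)
}

#' Write genotypes as a minimal VCF (GT + DS fields)
#'
#' Hard-call dosages are written as phased-free GT codes; fractional
#' dosages keep their value in DS with GT set from the rounded call.
#'
#' @inheritParams write_dosage_tsv
#' @export
write_vcf <- function(geno, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">", con)
  writeLines("##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">", con)
  for (nm in names(provenance)) {
    writeLines(sprintf("##%s=%s", nm, provenance[[nm]]), con)
  }
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", geno$samples), collapse = "\t"), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(geno$snps))) {
    d <- geno$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[pmin(pmax(round(d), 0), 2) + 1])
    ds <- ifelse(is.na(d), ".", formatC(d, format = "g", digits = 8))
    s <- geno$snps[j, ]
    writeLines(paste(c(s$chrom, s$pos, s$snp_id, s$ref_allele, s$alt_allele,
                       ".", "PASS", ".", "GT:DS", paste(gt, ds, sep = ":")),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a probe matrix with its annotation
#'
#' The matrix file has one row per probe (first column \code{probe_id},
#' remaining columns samples); the annotation file has columns
#' \code{probe_id}, \code{chrom}, \code{anchor_pos} and optionally
#' \code{gene_symbol}. Every probe in the matrix must be annotated.
#'
#' @param path matrix TSV.
#' @param annotation_path annotation TSV.
#' @param value_kind see \code{\link{probe_matrix}}.
#' @return A \code{\link{probe_matrix}}.
#' @export
read_probe_matrix <- function(path, annotation_path, value_kind = "beta") {
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  ann <- utils::read.delim(annotation_path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "probe_id") stop("matrix first column must be probe_id")
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("probe matrix values not parseable as reals")
  rownames(vals) <- tab$probe_id
  unann <- setdiff(tab$probe_id, ann$probe_id)
  if (length(unann)) {
    stop("probes without annotation: ",
         paste(utils::head(unann, 10), collapse = ", "))
  }
  ann <- ann[match(tab$probe_id, ann$probe_id), ]
  probe_matrix(colnames(vals), ann, t(vals), value_kind)
}

#' Write a probe matrix (and optionally its annotation)
#'
#' @param pm a \code{\link{probe_matrix}}.
#' @param path matrix TSV output.
#' @param annotation_path optional annotation TSV output.
#' @param provenance optional named list for the header.
#' @export
write_probe_matrix <- function(pm, path, annotation_path = NULL,
                               provenance = NULL) {
  tab <- cbind(data.frame(probe_id = pm$probes$probe_id), as.data.frame(t(pm$values)))
  write_tsv_with_header(tab, path, provenance)
  if (!is.null(annotation_path)) {
    write_tsv_with_header(pm$probes, annotation_path, provenance)
  }
  invisible(path)
}

#' Read a BED3/BED4 file as an interval track
#'
#' BED coordinates are 0-based half-open and are stored as given. The
#' track name is taken from a \code{track name=...} line when present,
#' otherwise from the file name.
#'
#' @param path_bed BED file.
#' @return An \code{\link{interval_track}}.
#' @export
read_track <- function(path_bed) {
  lines <- readLines(path_bed)
  name <- sub("\\.bed$", "", basename(path_bed))
  keep <- !grepl("^(#|browser)", lines) & nzchar(lines)
  tl <- grep("^track", lines)
  if (length(tl)) {
    m <- regmatches(lines[tl[1]], regexec("name=\"?([^\" ]+)\"?", lines[tl[1]]))[[1]]
    if (length(m) == 2) name <- m[2]
    keep[tl] <- FALSE
  }
  body <- lines[keep]
  if (!length(body)) {
    return(interval_track(name, data.frame(chrom = character(0),
                                           start = integer(0), end = integer(0))))
  }
  parts <- strsplit(body, "\t| +")
  n_fields <- lengths(parts)
  if (any(n_fields < 3)) {
    stop("BED line ", which(keep)[which(n_fields < 3)[1]], " has fewer than 3 fields")
  }
  iv <- data.frame(chrom = vapply(parts, `[[`, "", 1),
                   start = as.numeric(vapply(parts, `[[`, "", 2)),
                   end = as.numeric(vapply(parts, `[[`, "", 3)),
                   stringsAsFactors = FALSE)
  bad <- which(!(iv$start < iv$end))
  if (length(bad)) {
    stop("BED line ", which(keep)[bad[1]], ": start >= end")
  }
  interval_track(name, iv)
}

#' Write an interval track as BED3
#' @param track an \code{\link{interval_track}}.
#' @param path output BED file.
#' @export
write_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track name=\"%s\"", track$name), con)
  iv <- track$intervals
  if (nrow(iv)) {
    writeLines(paste(iv$chrom, format(iv$start, scientific = FALSE, trim = TRUE),
                     format(iv$end, scientific = FALSE, trim = TRUE), sep = "\t"), con)
  }
  invisible(path)
}

qtl_table_columns <- c("snp_id", "probe_id", "distance_bp", "beta", "se", "t",
                       "p", "fdr_significant", "r2_genotype", "r2_neuronal",
                       "r2_age", "r2_gender")

#' Write a QTL record table
#'
#' Rows are ordered by probe id and, within a probe, by ascending p-value;
#' the column order is fixed so downstream joins are stable.
#'
#' @param records data.frame of QTL records (see \code{\link{run_cis_scan}}).
#' @param path output TSV.
#' @param provenance optional named list for the \code{#} header.
#' @export
write_qtl_table <- function(records, path, provenance = NULL) {
  if (nrow(records)) {
    records <- records[order(records$probe_id, records$p), ]
  }
  missing_cols <- setdiff(qtl_table_columns, names(records))
  for (mc in missing_cols) records[[mc]] <- NA
  write_tsv_with_header(records[, qtl_table_columns, drop = FALSE], path, provenance)
}

#' Read a QTL record table written by \code{\link{write_qtl_table}}
#' @param path TSV file.
#' @return data.frame of QTL records.
#' @export
read_qtl_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a GWAS SNP list (snp_id, chrom, pos, p_value)
#' @param path TSV file.
#' @return data.frame; p-values validated to (0, 1].
#' @export
read_gwas_list <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "p_value")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("GWAS list missing columns: ", paste(miss, collapse = ", "))
  if (any(tab$p_value <= 0 | tab$p_value > 1)) stop("GWAS p-values must be in (0, 1]")
  tab
}

#' Read a covariate table (first column sample ids)
#' @param path TSV file.
#' @return data.frame with rownames set to sample ids.
#' @export
read_covariates <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  rownames(tab) <- tab[[1]]
  tab[[1]] <- NULL
  if (anyNA(tab)) stop("covariate table contains missing values")
  tab
}

write_tsv_with_header <- function(tab, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# meqtltools %s",
                     as.character(utils::packageVersion("meqtltools"))), con)
  for (nm in names(provenance)) {
    writeLines(sprintf("# %s: %s", nm, provenance[[nm]]), con)
  }
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a covariate table with sample-id first column
#' @param covariates data.frame with rownames = sample ids.
#' @param path output TSV.
#' @param provenance optional header list.
#' @export
write_covariates <- function(covariates, path, provenance = NULL) {
  tab <- cbind(data.frame(sample_id = rownames(covariates)), covariates)
  write_tsv_with_header(tab, path, provenance)
}

# restore the caller's RNG state after seeded draws, so generators are
# pure functions of (config, seed)
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
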