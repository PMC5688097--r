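# Synthetic cohort generator.
#
# Emulates the statistical structure the cis-QTL analysis assumes: block-LD
# genotype dosages with MAF above a floor, bimodal CpG beta-values produced
# by a logistic-liability model, Gaussian log2 expression, demographic and
# cell-composition covariates, annotation tracks with a planted coverage
# odds ratio for QTL-CpGs, and GWAS SNP lists with a planted LD overlap.
# All generators are pure functions of (config, seed): the caller's RNG
# state is left untouched.

#' Simulation configuration
#'
#' Defaults describe the cohort conditions the pipeline is designed for:
#' 110 samples, SNPs with MAF above 5\% in LD blocks, CpG classes with an
#' excess of fully methylated and unmethylated sites, planted cis effects
#' expressed as variance fractions, and covariate effects of roughly 5\%
#' (neuronal proportion), 3\% (age) and 1\% (gender) of probe variance.
#'
#' @param n_samples number of individuals.
#' @param n_snps number of SNPs; must be divisible by \code{ld_block_size}.
#' @param ld_block_size SNPs per LD block.
#' @param within_block_r2_target target pairwise dosage r-squared within a
#'   block, in \[0, 0.98\].
#' @param maf_range allele-frequency range the blocks are drawn from; the
#'   empirical MAF of every column is kept inside this range by resampling.
#' @param n_cpg_probes,n_expr_probes probe counts.
#' @param planted_meqtls,planted_eqtls data.frames with columns
#'   \code{snp} (column index into the genotype matrix), \code{probe}
#'   (probe index) and \code{variance_explained} in (0, 1).
#' @param covariate_variance named list of per-probe variance fractions for
#'   \code{neuronal}, \code{age} and \code{gender}.
#' @param bimodal_mixture weights of the (unmethylated, intermediate,
#'   methylated) CpG classes; must sum to 1.
#' @param seed master seed for the cohort.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_samples = 110,
                       n_snps = 500,
                       ld_block_size = 10,
                       within_block_r2_target = 0.8,
                       maf_range = c(0.05, 0.5),
                       n_cpg_probes = 200,
                       n_expr_probes = 100,
                       planted_meqtls = NULL,
                       planted_eqtls = NULL,
                       covariate_variance = list(neuronal = 0.05,
                                                 age = 0.03,
                                                 gender = 0.01),
                       bimodal_mixture = c(0.45, 0.10, 0.45),
                       seed = 1L) {
  if (n_snps %% ld_block_size != 0) {
    stop("n_snps must be divisible by ld_block_size")
  }
  if (within_block_r2_target < 0 || within_block_r2_target > 0.98) {
    stop("within_block_r2_target must lie in [0, 0.98]")
  }
  if (abs(sum(bimodal_mixture) - 1) > 1e-8) {
    stop("bimodal_mixture weights must sum to 1")
  }
  cv <- sum(unlist(covariate_variance))
  check_planted <- function(pl, n_probes) {
    if (is.null(pl) || !nrow(pl)) return(invisible())
    if (any(pl$variance_explained <= 0 | pl$variance_explained >= 1)) {
      stop("variance_explained must lie in (0, 1)")
    }
    if (any(pl$variance_explained + cv >= 1)) {
      stop("variance fractions (effect + covariates) must sum to < 1 per probe")
    }
    if (any(pl$snp < 1 | pl$snp > n_snps)) stop("planted SNP index out of range")
    if (any(pl$probe < 1 | pl$probe > n_probes)) stop("planted probe index out of range")
    if (anyDuplicated(pl$probe)) stop("at most one planted effect per probe")
  }
  check_planted(planted_meqtls, n_cpg_probes)
  check_planted(planted_eqtls, n_expr_probes)
  structure(list(n_samples = n_samples, n_snps = n_snps,
                 ld_block_size = ld_block_size,
                 within_block_r2_target = within_block_r2_target,
                 maf_range = maf_range,
                 n_cpg_probes = n_cpg_probes, n_expr_probes = n_expr_probes,
                 planted_meqtls = planted_meqtls, planted_eqtls = planted_eqtls,
                 covariate_variance = covariate_variance,
                 bimodal_mixture = bimodal_mixture,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate block-LD genotype dosages
#'
#' Each LD block shares one allele frequency. Per sample, a pair of latent
#' haplotype anchor alleles is drawn for the block; every SNP in the block
#' copies the anchor allele with probability \eqn{c} and otherwise redraws
#' a fresh allele at the block frequency. Two SNPs in a block then have
#' allelic correlation \eqn{c^2}, so \eqn{c} is set to
#' \code{within_block_r2_target^(1/4)} to hit the requested dosage
#' r-squared. SNPs sit on one synthetic chromosome at fixed 2 kb spacing;
#' columns whose empirical MAF falls outside \code{maf_range} are redrawn.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed overrides \code{config$seed} when given.
#' @return A \code{\link{genotype_matrix}}; the annotation carries a
#'   \code{block} column with the LD-block index of every SNP.
#' @export
simulate_genotypes <- function(config, seed = config$seed) {
  local_seed(seed, {
    n <- config$n_samples
    m <- config$n_snps
    bs <- config$ld_block_size
    n_blocks <- m %/% bs
    copy_p <- config$within_block_r2_target^(1 / 4)
    dosage <- matrix(NA_real_, n, m)
    block_of <- rep(seq_len(n_blocks), each = bs)
    for (b in seq_len(n_blocks)) {
      p <- stats::runif(1, config$maf_range[1], config$maf_range[2])
      anchors <- matrix(stats::rbinom(2 * n, 1, p), n, 2)
      cols <- which(block_of == b)
      for (j in cols) {
        for (try in 1:200) {
          copy <- matrix(stats::rbinom(2 * n, 1, copy_p), n, 2)
          fresh <- matrix(stats::rbinom(2 * n, 1, p), n, 2)
          hap <- copy * anchors + (1 - copy) * fresh
          d <- rowSums(hap)
          maf <- maf_from_dosage(d)
          if (maf >= config$maf_range[1] && maf > 0) break
        }
        dosage[, j] <- d
      }
    }
    samples <- sprintf("S%03d", seq_len(n))
    snps <- data.frame(snp_id = sprintf("snp%05d", seq_len(m)),
                       chrom = "chr1",
                       pos = 2000L * seq_len(m),
                       ref_allele = "A", alt_allele = "G",
                       block = block_of,
                       stringsAsFactors = FALSE)
    genotype_matrix(samples, snps, dosage)
  })
}

# standardized dosage column (mean-imputed, unit variance)
std_dosage <- function(d) {
  d[is.na(d)] <- mean(d, na.rm = TRUE)
  as.numeric(scale(d))
}

# per-probe covariate contribution on the liability scale plus the noise
# standard deviation completing unit variance
covariate_liability <- function(covariates, config, n_probes) {
  cv <- config$covariate_variance
  cols <- list(neuronal = as.numeric(scale(covariates$neuronal_proportion)),
               age = as.numeric(scale(covariates$age_years)),
               gender = as.numeric(scale(covariates$gender)))
  n <- nrow(covariates)
  contrib <- matrix(0, n, n_probes)
  for (nm in names(cols)) {
    v <- cv[[nm]]
    if (is.null(v) || v == 0) next
    signs <- sample(c(-1, 1), n_probes, replace = TRUE)
    contrib <- contrib + outer(cols[[nm]], signs * sqrt(v))
  }
  list(contrib = contrib, var_used = sum(unlist(cv)))
}

#' Simulate a CpG methylation beta-value matrix
#'
#' Each CpG has a latent Gaussian liability (planted allelic effect +
#' covariate effects + noise) that is mapped through the inverse logit and
#' shifted per mixture class, so the background medians are bimodal with
#' modes near 0 and 1. Planted CpGs are assigned to the intermediate class
#' (QTL-CpGs empirically show intermediate methylation), where the inverse
#' logit is close to linear, so the liability-scale variance fraction
#' carries over to the beta scale essentially unattenuated; the noise
#' component is orthogonalized against the dosage in-sample so the
#' realized genotype share matches \code{variance_explained} up to
#' sampling error in the covariate draw.
#'
#' @param genotypes a \code{\link{genotype_matrix}} from
#'   \code{\link{simulate_genotypes}}.
#' @param config a \code{\link{sim_config}}.
#' @param covariates covariate table from \code{\link{make_covariates}};
#'   generated internally when omitted.
#' @param seed RNG seed.
#' @return A beta-value \code{\link{probe_matrix}} with attribute
#'   \code{"planted"}: data.frame of (probe_id, snp_id, variance_explained).
#' @export
simulate_methylation <- function(genotypes, config, covariates = NULL,
                                 seed = config$seed + 1L) {
  if (is.null(covariates)) {
    covariates <- make_covariates(config$n_samples, seed = config$seed + 3L)
  }
  local_seed(seed, {
    n <- length(genotypes$samples)
    np <- config$n_cpg_probes
    shifts <- c(-3, 0, 3)
    class_of <- sample(1:3, np, replace = TRUE, prob = config$bimodal_mixture)
    max_pos <- max(genotypes$snps$pos)
    anchor <- sample.int(max_pos, np, replace = TRUE)
    planted <- config$planted_meqtls
    if (!is.null(planted) && nrow(planted)) {
      class_of[planted$probe] <- 2L
      offs <- sample(c(-1, 1), nrow(planted), replace = TRUE) *
        sample(500:50000, nrow(planted), replace = TRUE)
      anchor[planted$probe] <- pmax(1L, genotypes$snps$pos[planted$snp] + offs)
    }
    cl <- covariate_liability(covariates, config, np)
    noise_sd <- sqrt(1 - cl$var_used)
    liability <- cl$contrib + matrix(stats::rnorm(n * np, sd = noise_sd), n, np)
    beta <- stats::plogis(sweep(liability, 2, shifts[class_of], "+"))
    if (!is.null(planted) && nrow(planted)) {
      # squash scale for planted liabilities: keeps the inverse logit in
      # its near-linear range even for rare-homozygote dosage levels, so
      # the beta-scale genotype share tracks variance_explained closely
      s <- 0.4
      for (k in seq_len(nrow(planted))) {
        j <- planted$probe[k]
        v <- planted$variance_explained[k]
        g <- std_dosage(genotypes$dosage[, planted$snp[k]])
        # rebuild this probe's liability: allelic effect + covariates +
        # dosage-orthogonal noise completing unit variance
        noise <- stats::rnorm(n)
        noise <- as.numeric(scale(stats::lm.fit(cbind(1, g), noise)$residuals))
        nv <- max(1 - v - cl$var_used, 0)
        z <- sqrt(v) * g + cl$contrib[, j] + sqrt(nv) * noise
        beta[, j] <- stats::plogis(s * z + shifts[class_of[j]])
      }
    }
    probes <- data.frame(probe_id = sprintf("cpg%05d", seq_len(np)),
                         chrom = "chr1", anchor_pos = anchor,
                         gene_symbol = NA_character_,
                         stringsAsFactors = FALSE)
    pm <- probe_matrix(genotypes$samples, probes, beta, "beta")
    truth <- if (!is.null(planted) && nrow(planted)) {
      data.frame(probe_id = probes$probe_id[planted$probe],
                 snp_id = genotypes$snps$snp_id[planted$snp],
                 variance_explained = planted$variance_explained,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(probe_id = character(0), snp_id = character(0),
                 variance_explained = numeric(0))
    }
    attr(pm, "planted") <- truth
    pm
  })
}

#' Simulate a log2 expression matrix
#'
#' Gaussian analogue of \code{\link{simulate_methylation}}: no logistic
#' transform, values on a log2 scale centred at 8. Planted transcripts get
#' an additive allelic effect explaining \code{variance_explained} of the
#' unit liability variance. Shared-driver triples are obtained by planting
#' the same SNP index in \code{planted_meqtls} and \code{planted_eqtls}.
#'
#' @inheritParams simulate_methylation
#' @return A \code{log2_expression} \code{\link{probe_matrix}} with a
#'   \code{"planted"} attribute as in \code{\link{simulate_methylation}}.
#' @export
simulate_expression <- function(genotypes, config, covariates = NULL,
                                seed = config$seed + 2L) {
  if (is.null(covariates)) {
    covariates <- make_covariates(config$n_samples, seed = config$seed + 3L)
  }
  local_seed(seed, {
    n <- length(genotypes$samples)
    np <- config$n_expr_probes
    max_pos <- max(genotypes$snps$pos)
    anchor <- sample.int(max_pos, np, replace = TRUE)
    planted <- config$planted_eqtls
    cl <- covariate_liability(covariates, config, np)
    g_effect <- matrix(0, n, np)
    noise_var <- rep(1 - cl$var_used, np)
    if (!is.null(planted) && nrow(planted)) {
      offs <- sample(c(-1, 1), nrow(planted), replace = TRUE) *
        sample(1000:100000, nrow(planted), replace = TRUE)
      anchor[planted$probe] <- pmax(1L, genotypes$snps$pos[planted$snp] + offs)
      for (k in seq_len(nrow(planted))) {
        j <- planted$probe[k]
        g <- std_dosage(genotypes$dosage[, planted$snp[k]])
        g_effect[, j] <- sqrt(planted$variance_explained[k]) * g
        noise_var[j] <- noise_var[j] - planted$variance_explained[k]
      }
    }
    noise <- matrix(stats::rnorm(n * np), n, np) %*% diag(sqrt(noise_var), np)
    values <- 8 + g_effect + cl$contrib + noise
    probes <- data.frame(probe_id = sprintf("tx%05d", seq_len(np)),
                         chrom = "chr1", anchor_pos = anchor,
                         gene_symbol = sprintf("GENE%04d", seq_len(np)),
                         stringsAsFactors = FALSE)
    pm <- probe_matrix(genotypes$samples, probes, values, "log2_expression")
    truth <- if (!is.null(planted) && nrow(planted)) {
      data.frame(probe_id = probes$probe_id[planted$probe],
                 snp_id = genotypes$snps$snp_id[planted$snp],
                 variance_explained = planted$variance_explained,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(probe_id = character(0), snp_id = character(0),
                 variance_explained = numeric(0))
    }
    attr(pm, "planted") <- truth
    pm
  })
}

#' Simulate an annotation track with planted CpG enrichment
#'
#' Each CpG is covered by the track with probability \eqn{q} (QTL-CpGs) or
#' \eqn{p} (background CpGs) where \eqn{odds(q)/odds(p)} equals
#' \code{enrichment_odds}; covered CpGs contribute a +/-100 bp interval.
#'
#' @param probe_ann probe annotation data.frame (probe_id, chrom,
#'   anchor_pos).
#' @param qtl_flags logical vector marking QTL-CpGs.
#' @param enrichment_odds planted odds ratio (> 0); 1 gives a null track.
#' @param seed RNG seed.
#' @param background_rate coverage probability for background CpGs.
#' @param name track name.
#' @return An \code{\link{interval_track}}.
#' @export
simulate_tracks <- function(probe_ann, qtl_flags, enrichment_odds, seed,
                            background_rate = 0.15, name = "sim_track") {
  if (enrichment_odds <= 0) stop("enrichment_odds must be > 0")
  p <- background_rate
  odds_q <- enrichment_odds * p / (1 - p)
  q <- odds_q / (1 + odds_q)
  if (p <= 0 || p >= 1 || q <= 0 || q >= 1) {
    stop("coverage probabilities must lie in (0, 1)")
  }
  local_seed(seed, {
    pr <- ifelse(qtl_flags, q, p)
    covered <- stats::rbinom(nrow(probe_ann), 1, pr) == 1
    iv <- data.frame(chrom = probe_ann$chrom[covered],
                     start = pmax(0, probe_ann$anchor_pos[covered] - 101),
                     end = probe_ann$anchor_pos[covered] + 100,
                     stringsAsFactors = FALSE)
    interval_track(name, iv)
  })
}

#' Simulate a GWAS hit list with planted LD overlap
#'
#' Draws \code{n_hits} quasi-independent GWAS SNPs, one per LD block: a
#' fraction \code{overlap_fraction} from blocks containing QTL-SNPs
#' (so they are LD proxies of QTL-SNPs), the rest from QTL-free blocks.
#' P-values are drawn below genome-wide significance (5e-8).
#'
#' @param genotypes a \code{\link{genotype_matrix}} with a \code{block}
#'   annotation column.
#' @param qtl_snps character vector of QTL-SNP ids.
#' @param n_hits number of GWAS SNPs.
#' @param overlap_fraction fraction in \[0, 1\] drawn from QTL blocks.
#' @param seed RNG seed.
#' @return data.frame (snp_id, chrom, pos, p_value).
#' @export
simulate_gwas_list <- function(genotypes, qtl_snps, n_hits, overlap_fraction,
                               seed) {
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop("overlap_fraction must lie in [0, 1]")
  }
  if (is.null(genotypes$snps$block)) {
    stop("genotype annotation lacks LD-block labels")
  }
  blocks <- genotypes$snps$block
  qtl_blocks <- unique(blocks[genotypes$snps$snp_id %in% qtl_snps])
  free_blocks <- setdiff(unique(blocks), qtl_blocks)
  n_in <- round(n_hits * overlap_fraction)
  n_out <- n_hits - n_in
  if (n_in > length(qtl_blocks) || n_out > length(free_blocks)) {
    stop("n_hits exceeds available LD blocks")
  }
  local_seed(seed, {
    pick_block <- c(sample(qtl_blocks, n_in),
                    sample(free_blocks, n_out))
    idx <- vapply(pick_block, function(b) {
      cand <- which(blocks == b)
      cand[sample.int(length(cand), 1)]
    }, integer(1))
    data.frame(snp_id = genotypes$snps$snp_id[idx],
               chrom = genotypes$snps$chrom[idx],
               pos = genotypes$snps$pos[idx],
               p_value = 10^-stats::runif(n_hits, 8.05, 15),
               stringsAsFactors = FALSE)
  })
}

#' Simulate sample covariates
#'
#' Gender is Bernoulli(0.5), age uniform on \[1, 67\] years, and the
#' neuronal cell proportion Beta(2, 2)-distributed rescaled to
#' \[0.2, 0.8\].
#'
#' @param n_samples number of samples (>= 2).
#' @param seed RNG seed.
#' @return data.frame with rownames = sample ids and columns
#'   \code{gender}, \code{age_years}, \code{neuronal_proportion}.
#' @export
make_covariates <- function(n_samples, seed) {
  if (n_samples < 2) stop("need at least 2 samples")
  local_seed(seed, {
    tab <- data.frame(gender = stats::rbinom(n_samples, 1, 0.5),
                      age_years = stats::runif(n_samples, 1, 67),
                      neuronal_proportion = 0.2 + 0.6 * stats::rbeta(n_samples, 2, 2))
    rownames(tab) <- sprintf("S%03d", seq_len(n_samples))
    tab
  })
}

#' Simulate a complete aligned cohort
#'
#' Convenience wrapper generating genotypes, covariates, methylation and
#' expression with sub-seeds derived from the config's master seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with elements \code{genotypes}, \code{covariates},
#'   \code{methylation}, \code{expression}, \code{truth_meqtl},
#'   \code{truth_eqtl}.
#' @export
simulate_cohort <- function(config) {
  geno <- simulate_genotypes(config)
  covs <- make_covariates(config$n_samples, seed = config$seed + 3L)
  meth <- simulate_methylation(geno, config, covs)
  expr <- simulate_expression(geno, config, covs)
  list(genotypes = geno, covariates = covs,
       methylation = meth, expression = expr,
       truth_meqtl = attr(meth, "planted"),
       truth_eqtl = attr(expr, "planted"))
}
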