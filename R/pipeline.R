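# End-to-end orchestration over a synthetic cohort: simulate -> QC ->
# covariate assembly -> cis scans -> methylation-expression correlation
# -> annotation enrichment -> LD-overlap enrichment. Each stage is a pure
# function of its inputs and a stage seed derived from the master seed by
# a fixed per-stage offset, so identical (config, seed) reproduce
# byte-identical outputs and inserting a stage never perturbs another
# stage's randomness. Stage outputs are written as TSV/YAML under the
# output directory together with an md5 manifest.

pipeline_stage_order <- c("simulate", "qc", "scan_meqtl", "scan_eqtl",
                          "correlate", "enrich_annotation", "enrich_ld")

# fixed offsets: inserting a new stage gets a new offset, existing ones
# keep theirs
pipeline_stage_offsets <- c(simulate = 101L, qc = 211L, scan_meqtl = 307L,
                            scan_eqtl = 401L, correlate = 503L,
                            enrich_annotation = 601L, enrich_ld = 701L)

stage_seed <- function(master_seed, stage) {
  (as.integer(master_seed) %% 1000000L) * 1000L + pipeline_stage_offsets[[stage]]
}

#' Validate and complete a pipeline configuration
#'
#' Accepts a named list or a YAML file path; fills defaults for every
#' missing parameter and performs type/range checks, reporting all
#' violations at once. Defaults are the pipeline's standard analysis
#' settings: 500 kb cis window, 1\% FDR, clumping at r-squared 0.25
#' within 250 kb, seven-fold beta matching.
#'
#' @param config named list or path to a YAML file; NULL gives the fully
#'   defaulted configuration.
#' @return completed configuration list of class \code{run_config}.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  defaults <- list(
    n_samples = 110, n_snps = 600, ld_block_size = 10,
    within_block_r2_target = 0.8, n_cpg_probes = 600, n_expr_probes = 150,
    n_planted_meqtl = 15, n_planted_eqtl = 8, n_shared_drivers = 4,
    window_kb = 500, fdr = 0.01,
    n_genotype_pcs = 3, n_hidden_pcs_meth = 3, n_hidden_pcs_expr = 2,
    clump_r2 = 0.25, clump_window_kb = 250,
    overlap_r2 = 0.25, overlap_window_kb = 250,
    match_ratio = 7, maf_bin_width = 0.1,
    annotation_odds = 1.8, n_tracks = 5,
    gwas_n_hits = 25, gwas_overlap_fraction = 0.5,
    n_sets = 500, seed = 1L,
    stages = pipeline_stage_order)
  unknown <- setdiff(names(config), names(defaults))
  cfg <- utils::modifyList(defaults, config[setdiff(names(config), unknown)])
  errors <- character(0)
  if (length(unknown)) {
    errors <- c(errors, paste("unknown parameter(s):", paste(unknown, collapse = ", ")))
  }
  chk <- function(ok, msg) if (!ok) errors <<- c(errors, msg)
  chk(cfg$fdr > 0 && cfg$fdr < 1, "fdr must lie in (0, 1)")
  chk(cfg$window_kb > 0, "window_kb must be positive")
  chk(cfg$clump_r2 > 0 && cfg$clump_r2 < 1, "clump_r2 must lie in (0, 1)")
  chk(cfg$overlap_r2 > 0 && cfg$overlap_r2 < 1, "overlap_r2 must lie in (0, 1)")
  chk(cfg$clump_window_kb > 0, "clump_window_kb must be positive")
  chk(cfg$overlap_window_kb > 0, "overlap_window_kb must be positive")
  chk(cfg$n_samples >= 10, "n_samples must be >= 10")
  chk(cfg$match_ratio >= 1, "match_ratio must be >= 1")
  chk(cfg$n_sets >= 100, "n_sets must be >= 100")
  chk(cfg$annotation_odds > 0, "annotation_odds must be positive")
  chk(cfg$gwas_overlap_fraction >= 0 && cfg$gwas_overlap_fraction <= 1,
      "gwas_overlap_fraction must lie in [0, 1]")
  chk(cfg$within_block_r2_target >= 0 && cfg$within_block_r2_target <= 0.98,
      "within_block_r2_target must lie in [0, 0.98]")
  chk(all(cfg$stages %in% pipeline_stage_order),
      paste("stages must be among:", paste(pipeline_stage_order, collapse = ", ")))
  if (length(errors)) {
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  }
  structure(cfg, class = "run_config")
}

qc_report_table <- function(report) {
  data.frame(stage = report$stage,
             rule = c(names(report$n_removed_per_rule), "(input)", "(output)"),
             count = c(unname(report$n_removed_per_rule),
                       report$n_input, report$n_output),
             stringsAsFactors = FALSE)
}

# largest per-bin control:target ratio the pool supports, given a binning
feasible_ratio <- function(target_bins, pool_bins, requested) {
  need <- table(target_bins)
  avail <- table(pool_bins)[names(need)]
  avail[is.na(avail)] <- 0
  min(requested, floor(min(avail / need)))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes the requested stages in dependency order, writing each
#' stage's outputs (TSV with \code{#} provenance headers, YAML
#' summaries) under \code{out_dir}, and finishes with an md5 manifest of
#' every written file plus the configuration hash. Stages not requested
#' must have left their outputs in \code{out_dir} from a previous run;
#' otherwise a pre-flight error names the missing stage.
#'
#' @param config a \code{\link{validate_config}} result, raw list, or
#'   YAML path.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = NULL, out_dir) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- intersect(pipeline_stage_order, cfg$stages)
  written <- character(0)
  note <- function(path) written <<- c(written, path)
  path_of <- function(f) file.path(out_dir, f)
  prov <- function(stage) list(seed = stage_seed(cfg$seed, stage), stage = stage)

  # pre-flight: every requested stage needs its upstream outputs, either
  # from an earlier requested stage or on disk
  deps <- list(simulate = character(0),
               qc = "simulate",
               scan_meqtl = "qc", scan_eqtl = "qc",
               correlate = "qc",
               enrich_annotation = c("qc", "scan_meqtl"),
               enrich_ld = c("qc", "scan_meqtl"))
  stage_marker <- c(simulate = "genotypes_dosage.tsv", qc = "qc_beta.tsv",
                    scan_meqtl = "meqtl_records.tsv",
                    scan_eqtl = "eqtl_records.tsv",
                    correlate = "correlations.tsv",
                    enrich_annotation = "annotation_enrichment.tsv",
                    enrich_ld = "ld_overlap_enrichment.tsv")
  for (st in stages) {
    for (dep in deps[[st]]) {
      if (!(dep %in% stages) && !file.exists(path_of(stage_marker[[dep]]))) {
        stop("pre-flight: stage '", st, "' requires outputs of stage '",
             dep, "' which is neither requested nor cached in ", out_dir)
      }
    }
  }

  state <- new.env(parent = emptyenv())

  ## ---- simulate ----
  if ("simulate" %in% stages) {
    sseed <- stage_seed(cfg$seed, "simulate")
    planted <- local_seed(sseed, {
      blocks <- seq_len(cfg$n_snps %/% cfg$ld_block_size)
      me_blocks <- sample(blocks, cfg$n_planted_meqtl)
      me_snp <- (me_blocks - 1L) * cfg$ld_block_size +
        sample.int(cfg$ld_block_size, cfg$n_planted_meqtl, replace = TRUE)
      me <- data.frame(snp = me_snp,
                       probe = sample.int(cfg$n_cpg_probes, cfg$n_planted_meqtl),
                       variance_explained = stats::runif(cfg$n_planted_meqtl, 0.10, 0.85))
      n_sh <- min(cfg$n_shared_drivers, cfg$n_planted_eqtl, cfg$n_planted_meqtl)
      eq_blocks <- sample(setdiff(blocks, me_blocks),
                          cfg$n_planted_eqtl - n_sh)
      eq_snp <- c(me_snp[seq_len(n_sh)],
                  (eq_blocks - 1L) * cfg$ld_block_size +
                    sample.int(cfg$ld_block_size, cfg$n_planted_eqtl - n_sh,
                               replace = TRUE))
      eq <- data.frame(snp = eq_snp,
                       probe = sample.int(cfg$n_expr_probes, cfg$n_planted_eqtl),
                       variance_explained = stats::runif(cfg$n_planted_eqtl, 0.16, 0.80))
      list(me = me, eq = eq)
    })
    sc <- sim_config(n_samples = cfg$n_samples, n_snps = cfg$n_snps,
                     ld_block_size = cfg$ld_block_size,
                     within_block_r2_target = cfg$within_block_r2_target,
                     n_cpg_probes = cfg$n_cpg_probes,
                     n_expr_probes = cfg$n_expr_probes,
                     planted_meqtls = planted$me, planted_eqtls = planted$eq,
                     seed = sseed)
    cohort <- simulate_cohort(sc)
    state$geno <- cohort$genotypes
    state$meth <- cohort$methylation
    state$expr <- cohort$expression
    state$covs <- cohort$covariates
    state$truth_meqtl <- cohort$truth_meqtl
    state$truth_eqtl <- cohort$truth_eqtl
    note(write_dosage_tsv(state$geno, path_of("genotypes_dosage.tsv"), prov("simulate")))
    note(write_vcf(state$geno, path_of("genotypes.vcf"),
                   list(meqtltools_seed = sseed)))
    note(write_probe_matrix(state$meth, path_of("methylation_beta.tsv"),
                            path_of("cpg_annotation.tsv"), prov("simulate")))
    note(path_of("cpg_annotation.tsv"))
    note(write_probe_matrix(state$expr, path_of("expression_log2.tsv"),
                            path_of("expr_annotation.tsv"), prov("simulate")))
    note(path_of("expr_annotation.tsv"))
    note(write_covariates(state$covs, path_of("covariates.tsv"), prov("simulate")))
    note(write_tsv_with_header(state$truth_meqtl, path_of("truth_meqtl.tsv"),
                               prov("simulate")))
    note(write_tsv_with_header(state$truth_eqtl, path_of("truth_eqtl.tsv"),
                               prov("simulate")))
  }

  load_simulated <- function() {
    if (is.null(state$geno)) {
      state$geno <- read_genotypes(path_of("genotypes_dosage.tsv"), "dosage_tsv")
      state$meth <- read_probe_matrix(path_of("methylation_beta.tsv"),
                                      path_of("cpg_annotation.tsv"), "beta")
      state$expr <- read_probe_matrix(path_of("expression_log2.tsv"),
                                      path_of("expr_annotation.tsv"),
                                      "log2_expression")
      state$covs <- read_covariates(path_of("covariates.tsv"))
      state$truth_meqtl <- utils::read.delim(path_of("truth_meqtl.tsv"),
                                             comment.char = "#")
      state$truth_eqtl <- utils::read.delim(path_of("truth_eqtl.tsv"),
                                            comment.char = "#")
    }
  }

  ## ---- qc ----
  if ("qc" %in% stages) {
    load_simulated()
    sq <- snp_qc(state$geno, call_rate_min = 0.97, maf_min = 0.01,
                 hwe_p_min = 1e-6)
    state$geno_qc <- sq$genotypes
    cq <- filter_cpg_probes(state$meth,
                            snp_annotation = state$geno_qc$snps,
                            cis_window = cfg$window_kb * 1000)
    state$meth_qc <- cq$probes
    state$expr_qc <- state$expr
    note(write_tsv_with_header(qc_report_table(sq$report),
                               path_of("qc_snp_report.tsv"), prov("qc")))
    note(write_tsv_with_header(qc_report_table(cq$report),
                               path_of("qc_cpg_report.tsv"), prov("qc")))
    note(write_probe_matrix(state$meth_qc, path_of("qc_beta.tsv"),
                            path_of("qc_cpg_annotation.tsv"), prov("qc")))
    note(path_of("qc_cpg_annotation.tsv"))
    note(write_dosage_tsv(state$geno_qc, path_of("qc_genotypes.tsv"), prov("qc")))
  }

  load_qc <- function() {
    load_simulated()
    if (is.null(state$geno_qc)) {
      state$geno_qc <- read_genotypes(path_of("qc_genotypes.tsv"), "dosage_tsv")
      state$meth_qc <- read_probe_matrix(path_of("qc_beta.tsv"),
                                         path_of("qc_cpg_annotation.tsv"), "beta")
      state$expr_qc <- state$expr
    }
  }

  known_covs <- function() {
    state$covs[, c("gender", "age_years", "neuronal_proportion"), drop = FALSE]
  }

  scan_stage <- function(probe_mat, n_hidden, records_file, summary_file, stage) {
    geno_pcs <- compute_genotype_pcs(state$geno_qc, cfg$n_genotype_pcs)
    resid <- residualize(probe_mat, known_covs())
    hidden <- hidden_confounder_pcs(resid, n_hidden)
    covariates <- cbind(known_covs(), geno_pcs, hidden)
    scan <- run_cis_scan(state$geno_qc, probe_mat, covariates,
                         scan_config(cfg$window_kb * 1000, cfg$fdr))
    note(write_qtl_table(scan$records, path_of(records_file), prov(stage)))
    yaml::write_yaml(scan$summary, path_of(summary_file))
    note(path_of(summary_file))
    scan
  }

  if ("scan_meqtl" %in% stages) {
    load_qc()
    state$scan_meqtl <- scan_stage(state$meth_qc, cfg$n_hidden_pcs_meth,
                                   "meqtl_records.tsv", "meqtl_summary.yaml",
                                   "scan_meqtl")
  }
  if ("scan_eqtl" %in% stages) {
    load_qc()
    state$scan_eqtl <- scan_stage(state$expr_qc, cfg$n_hidden_pcs_expr,
                                  "eqtl_records.tsv", "eqtl_summary.yaml",
                                  "scan_eqtl")
  }

  load_scan <- function(which) {
    slot <- paste0("scan_", which)
    if (is.null(state[[slot]])) {
      rec <- read_qtl_table(path_of(paste0(which, "_records.tsv")))
      ann <- if (which == "meqtl") state$meth_qc$probes else state$expr_qc$probes
      rec$snp_pos <- state$geno_qc$snps$pos[match(rec$snp_id, state$geno_qc$snps$snp_id)]
      state[[slot]] <- list(records = rec)
    }
  }

  ## ---- correlate ----
  if ("correlate" %in% stages) {
    load_qc()
    meth_res <- residualize(state$meth_qc, known_covs())
    expr_res <- residualize(state$expr_qc, known_covs())
    corr <- correlate_cis(meth_res, expr_res, cfg$window_kb * 1000, cfg$fdr)
    state$correlations <- corr
    note(write_tsv_with_header(corr, path_of("correlations.tsv"),
                               prov("correlate")))
    if (!is.null(state$scan_meqtl) && !is.null(state$scan_eqtl)) {
      drivers <- find_shared_drivers(state$scan_meqtl$records,
                                     state$scan_eqtl$records,
                                     corr, state$geno_qc, r2_min = 0.4)
      state$shared_drivers <- drivers
      note(write_tsv_with_header(drivers, path_of("shared_drivers.tsv"),
                                 prov("correlate")))
    }
  }

  ## ---- enrich_annotation ----
  if ("enrich_annotation" %in% stages) {
    load_qc()
    load_scan("meqtl")
    rec <- state$scan_meqtl$records
    sig_probes <- unique(rec$probe_id[rec$fdr_significant])
    ann <- state$meth_qc$probes
    med_beta <- apply(state$meth_qc$values, 2, stats::median, na.rm = TRUE)
    # control pool: CpGs whose best adjusted p exceeds 10% FDR
    adj <- stats::p.adjust(rec$p, "BH")
    min_adj <- tapply(adj, rec$probe_id, min)
    pool_ids <- names(min_adj)[min_adj > 0.10]
    pool_ids <- setdiff(pool_ids, sig_probes)
    is_qtl <- ann$probe_id %in% sig_probes
    eseed <- stage_seed(cfg$seed, "enrich_annotation")
    tracks <- lapply(seq_len(cfg$n_tracks), function(i) {
      simulate_tracks(ann, is_qtl, cfg$annotation_odds, seed = eseed + i,
                      name = sprintf("sim_track_%02d", i))
    })
    targets <- data.frame(probe_id = ann$probe_id, chrom = ann$chrom,
                          pos = ann$anchor_pos, match_beta = med_beta,
                          stringsAsFactors = FALSE)[is_qtl, ]
    pool <- data.frame(probe_id = ann$probe_id, chrom = ann$chrom,
                       pos = ann$anchor_pos, match_beta = med_beta,
                       stringsAsFactors = FALSE)
    pool <- pool[pool$probe_id %in% pool_ids, ]
    if (nrow(targets) && nrow(pool)) {
      ratio <- feasible_ratio(assign_beta_bins(targets$match_beta),
                              assign_beta_bins(pool$match_beta),
                              cfg$match_ratio)
      if (ratio < 1) stop("control pool cannot beta-match the meQTL-CpGs")
      enr <- run_annotation_enrichment(targets, pool, tracks,
                                       seed = eseed, match_ratio = ratio)
      enr$match_ratio_used <- ratio
      state$annotation_enrichment <- enr
      note(write_tsv_with_header(enr, path_of("annotation_enrichment.tsv"),
                                 prov("enrich_annotation")))
    } else {
      stop("annotation enrichment needs significant meQTL-CpGs and a control pool")
    }
  }

  ## ---- enrich_ld ----
  if ("enrich_ld" %in% stages) {
    load_qc()
    load_scan("meqtl")
    rec <- state$scan_meqtl$records
    adj <- stats::p.adjust(rec$p, "BH")
    snp_min_p <- tapply(rec$p, rec$snp_id, min)
    snp_min_adj <- tapply(adj, rec$snp_id, min)
    qtl_snps <- names(snp_min_adj)[snp_min_adj <= cfg$fdr]
    ctrl_snps <- names(snp_min_adj)[snp_min_adj > 0.10]
    lseed <- stage_seed(cfg$seed, "enrich_ld")
    # clamp the GWAS list to the block budget of this cohort
    blocks <- state$geno_qc$snps$block
    n_qtl_blocks <- length(unique(blocks[state$geno_qc$snps$snp_id %in% qtl_snps]))
    n_free_blocks <- length(unique(blocks)) - n_qtl_blocks
    n_in <- min(round(cfg$gwas_n_hits * cfg$gwas_overlap_fraction), n_qtl_blocks)
    n_out <- min(cfg$gwas_n_hits - n_in, n_free_blocks)
    n_hits <- n_in + n_out
    if (n_hits < 2) stop("too few LD blocks for a GWAS reference list")
    gwas <- simulate_gwas_list(state$geno_qc, qtl_snps, n_hits,
                               n_in / n_hits, seed = lseed)
    note(write_tsv_with_header(gwas, path_of("gwas_list.tsv"), prov("enrich_ld")))
    # adaptive MAF bin width: widen (deterministically) until the pool can
    # match every target bin, so desk-scale runs never abort on a sparse bin
    width <- cfg$maf_bin_width
    tgt <- data.frame(snp_id = qtl_snps,
                      maf = state$geno_qc$snps$maf[match(qtl_snps, state$geno_qc$snps$snp_id)])
    repeat {
      ok <- tryCatch({
        res <- run_overlap_enrichment(
          data.frame(snp_id = qtl_snps, p = snp_min_p[qtl_snps]),
          data.frame(snp_id = gwas$snp_id, p = gwas$p_value),
          data.frame(snp_id = ctrl_snps, p = snp_min_p[ctrl_snps]),
          state$geno_qc,
          clump_r2 = cfg$clump_r2,
          clump_window_bp = cfg$clump_window_kb * 1000,
          overlap_r2 = cfg$overlap_r2,
          overlap_window_bp = cfg$overlap_window_kb * 1000,
          n_sets = cfg$n_sets, exclude = NULL,
          maf_bin_width = width, seed = lseed + 1L)
        TRUE
      }, error = function(e) {
        if (grepl("MAF bin", conditionMessage(e)) && width < 0.5) FALSE else stop(e)
      })
      if (ok) break
      width <- width * 2
    }
    state$ld_enrichment <- res
    tab <- data.frame(n_target_clumped = res$n_target_clumped,
                      n_reference_clumped = res$n_reference_clumped,
                      observed_overlap = res$observed_overlap,
                      null_mean = res$null_mean, null_sd = res$null_sd,
                      error_of_mean = res$error_of_mean,
                      enrichment = res$enrichment,
                      empirical_p = res$empirical_p, n_sets = res$n_sets,
                      maf_bin_width_used = width)
    note(write_tsv_with_header(tab, path_of("ld_overlap_enrichment.tsv"),
                               prov("enrich_ld")))
  }

  ## ---- manifest ----
  cfg_path <- path_of("config.yaml")
  cfg_list <- unclass(cfg)
  yaml::write_yaml(cfg_list, cfg_path)
  note(cfg_path)
  files <- sort(unique(basename(written)))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir, files))),
                         stringsAsFactors = FALSE)
  config_hash <- unname(tools::md5sum(cfg_path))
  utils::write.table(rbind(manifest,
                           data.frame(file = "(config_hash)", md5 = config_hash)),
                     path_of("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(state = as.list(state), manifest = manifest,
                 config_hash = config_hash, out_dir = out_dir))
}
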