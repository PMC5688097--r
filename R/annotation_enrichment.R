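# Beta-value-matched Fisher enrichment of QTL-CpGs in annotation tracks:
# decile binning of median (or mean) beta-values, seven-fold matched
# control sampling without replacement, point overlap against 0-based
# half-open tracks, and an exact Fisher 2x2 with cross-product OR.

#' Assign beta-values to deciles
#'
#' Bin k covers \[(k-1)/10, k/10) with the final bin closed at 1, so
#' 0.10 falls in bin 2 and 1.0 in bin 10.
#'
#' @param median_betas numeric vector in \[0, 1\].
#' @return integer bin labels 1..10.
#' @export
assign_beta_bins <- function(median_betas) {
  if (any(median_betas < 0 | median_betas > 1, na.rm = TRUE)) {
    stop("beta values outside [0, 1]")
  }
  pmin(floor(median_betas * 10 + 1e-9) + 1L, 10L)
}

#' Sample beta-matched control CpGs
#'
#' Per beta decile, draws exactly \code{match_ratio} times the target
#' count from the control pool, without replacement.
#'
#' @param target_cpgs data.frame (probe_id, match_beta) of target CpGs;
#'   \code{match_beta} is the per-CpG median (or mean) beta-value.
#' @param control_pool data.frame (probe_id, match_beta) of candidate
#'   controls, disjoint from the targets.
#' @param match_ratio controls per target (default 7).
#' @param seed RNG seed.
#' @return character vector of control probe_ids.
#' @export
sample_matched_controls <- function(target_cpgs, control_pool,
                                    match_ratio = 7, seed = 1L) {
  if (any(target_cpgs$probe_id %in% control_pool$probe_id)) {
    stop("control pool must be disjoint from the target set")
  }
  tb <- assign_beta_bins(target_cpgs$match_beta)
  cb <- assign_beta_bins(control_pool$match_beta)
  need <- table(tb)
  pool_by_bin <- split(control_pool$probe_id, cb)
  for (b in names(need)) {
    want <- match_ratio * need[[b]]
    avail <- length(pool_by_bin[[b]])
    if (avail < want) {
      stop(sprintf("beta bin %s: pool has %d CpGs but %d required (shortfall %d)",
                   b, avail, want, want - avail))
    }
  }
  local_seed(seed, {
    unlist(lapply(names(need), function(b) {
      ids <- pool_by_bin[[b]]
      ids[sample.int(length(ids), match_ratio * need[[b]])]
    }), use.names = FALSE)
  })
}

#' Flag CpGs covered by an interval track
#'
#' A CpG (1-based coordinate) is flagged when it lies inside at least one
#' interval of the (0-based half-open) track.
#'
#' @param cpg_positions data.frame (chrom, pos).
#' @param track an \code{\link{interval_track}}.
#' @return logical vector.
#' @export
overlap_flags <- function(cpg_positions, track) {
  if (!nrow(track$intervals) || !nrow(cpg_positions)) {
    return(rep(FALSE, nrow(cpg_positions)))
  }
  q <- GenomicRanges::GRanges(seqnames = cpg_positions$chrom,
                              ranges = IRanges::IRanges(start = cpg_positions$pos,
                                                        width = 1))
  IRanges::overlapsAny(q, track_granges(track))
}

#' Fisher exact enrichment for a 2x2 table
#'
#' Odds ratio by the cross-product
#' \eqn{(a \cdot d)/(b \cdot c)} of the table
#' ((in_target, out_target), (in_control, out_control)); two-sided exact
#' p by the point-probability rule (sum of hypergeometric tables no more
#' probable than the observed one); 95\% CI by the log-OR normal
#' approximation. A zero cell triggers the 0.5 continuity correction for
#' the OR and CI and sets \code{continuity_corrected}.
#'
#' @param in_target,out_target,in_control,out_control non-negative
#'   integer counts; margins must be positive.
#' @return list (odds_ratio, ci95_low, ci95_high, p_value,
#'   ratio_target, ratio_control, continuity_corrected).
#' @export
fisher_enrichment <- function(in_target, out_target, in_control, out_control) {
  cells <- c(in_target, out_target, in_control, out_control)
  if (any(cells < 0)) stop("negative cell count")
  if (in_target + out_target == 0 || in_control + out_control == 0 ||
      in_target + in_control == 0 || out_target + out_control == 0) {
    stop("all margins of the 2x2 table must be positive")
  }
  corrected <- any(cells == 0)
  cc <- if (corrected) cells + 0.5 else cells
  or <- (cc[1] * cc[4]) / (cc[2] * cc[3])
  se_log <- sqrt(sum(1 / cc))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se_log)
  # exact two-sided p: condition on margins, sum P(k) <= P(observed)
  m <- in_target + in_control          # total "in track"
  nn <- out_target + out_control
  kk <- in_target + out_target         # target margin
  support <- max(0, kk - nn):min(kk, m)
  pr <- stats::dhyper(support, m, nn, kk)
  obs <- stats::dhyper(in_target, m, nn, kk)
  p <- min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
  list(odds_ratio = or, ci95_low = ci[1], ci95_high = ci[2], p_value = p,
       ratio_target = in_target / (in_target + out_target),
       ratio_control = in_control / (in_control + out_control),
       continuity_corrected = corrected)
}

#' Enrichment of target CpGs across annotation tracks
#'
#' Samples one beta-matched control set (fixed for all tracks), overlaps
#' targets and controls with every track, and reports the Fisher
#' enrichment per track with a Bonferroni q-value over the number of
#' tracks actually tested. Records are sorted by q.
#'
#' @param target_cpgs data.frame (probe_id, chrom, pos, match_beta).
#' @param control_pool data.frame of the same columns, disjoint from the
#'   targets.
#' @param tracks list of \code{\link{interval_track}} objects.
#' @param seed RNG seed for the control sampling.
#' @param match_ratio controls per target (default 7).
#' @return data.frame, one row per track: track_name, ratio_target,
#'   ratio_control, odds_ratio, ci95_low, ci95_high, p_value, q_value.
#' @export
run_annotation_enrichment <- function(target_cpgs, control_pool, tracks,
                                      seed = 1L, match_ratio = 7) {
  ctrl_ids <- sample_matched_controls(target_cpgs, control_pool,
                                      match_ratio, seed)
  ctrl <- control_pool[match(ctrl_ids, control_pool$probe_id), , drop = FALSE]
  n_tracks <- length(tracks)
  rows <- lapply(tracks, function(tr) {
    ft <- overlap_flags(target_cpgs, tr)
    fc <- overlap_flags(ctrl, tr)
    fe <- fisher_enrichment(sum(ft), sum(!ft), sum(fc), sum(!fc))
    data.frame(track_name = tr$name,
               ratio_target = fe$ratio_target,
               ratio_control = fe$ratio_control,
               odds_ratio = fe$odds_ratio,
               ci95_low = fe$ci95_low, ci95_high = fe$ci95_high,
               p_value = fe$p_value,
               q_value = min(1, fe$p_value * n_tracks),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$q_value, out$p_value), ]
}
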