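---
title: "Methods: cis-QTL mapping, enrichment machinery and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cis-QTL mapping, enrichment machinery and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meqtltools)
```

This vignette is the package's own account of its statistics: the linear
model behind the *cis*-QTL scan and its assumptions, the enrichment
machinery, what the synthetic-cohort generator does and does not emulate,
and the numerical and design choices that were genuinely open.

## The cis scan

A SNP–probe pair is *cis* when both sit on the same chromosome and the
distance between the SNP position and the probe anchor — the CpG
coordinate for methylation, the 5′-TSS for expression — is at most the
window half-width (default 500,000 bp, **boundary inclusive**; the
inclusive convention is applied identically in pair enumeration, the
probe-level "no SNP in the cis window" QC rule and the correlation
window, so boundary cases behave the same everywhere). Pairs are found by
a per-chromosome binary-search sweep, never an all-pairs product.

Each pair is fit by OLS of the phenotype on
`[intercept, dosage, covariates]`. The assumptions are the usual ones:
additive allelic effects, residuals that are approximately Gaussian and
homoscedastic, and covariates that enter linearly. β-values in [0, 1]
violate Gaussianity near the boundaries; the scan is nevertheless run on
the β scale, because per-allele effects in methylation units are the
quantity of scientific interest, and the FDR calibration suite shows the
joint BH procedure holds its level on bimodal null data at n = 110.

Covariates come in two passes. First the phenotype matrix is
residualized on the known confounders (gender, age in years, neuronal
cell proportion in [0, 1]); PCs of that residual matrix are then frozen
as unknown-confounder surrogates and entered as ordinary covariates next
to the known ones, three genotype PCs (columns standardized by
√(2p(1−p))), and — when a control-probe intensity matrix is available —
its leading PCs as technical-bias covariates. The default surrogate
counts are 3 (methylation) and 2 (expression), the points where the
residual-PC variance proportions flatten in cohorts of this size.

The scan itself residualizes both the phenotype matrix and the dosage
matrix on the full covariate set once and converts the per-pair residual
correlation r to t = r√(df/(1−r²)) with df = n − #covariates − 2. By the
Frisch–Waugh–Lovell theorem this equals the per-pair OLS t exactly; the
test suite asserts the identity against `lm()` at 10⁻⁸.

Multiple testing is Benjamini–Hochberg at FDR 1%, applied **jointly over
all cis pairs of a scan** (not per probe), which yields the single
data-dependent p threshold the summaries report. Methylation and
expression scans are corrected separately, each being its own family.

Per-covariate explained variance is reported as leave-one-term-out
ΔR² = R²(full) − R²(without the term), computed by refitting, with the
genotype share defined the same way and negative differences (possible
under non-orthogonality) clipped at zero. This decomposition is a
package choice; with near-orthogonal covariates it coincides with the
marginal R² up to sampling error, and the recovery suite shows planted
fractions {0.11, 0.24, 0.50, 0.85} come back within ±0.05 at n = 2000.

Missing dosages are mean-imputed per SNP at fit time only; the stored
matrix keeps its missing values so QC stays auditable. Monomorphic
dosages are skipped with a logged count, never fit.

## QC and normalization

SNPs pass QC when call rate, MAF and the **exact conditional
Hardy–Weinberg test** (not the χ² approximation, which misbehaves at the
small genotype counts a 110-sample cohort produces) all clear their
thresholds; removals are attributed to the first failing rule in that
order so reports are reproducible, and counts are conserved by
construction (`input = Σ removed + output`, asserted in the report
constructor). The CpG cascade applies, in order: detection p > 0.01 in
≥ 5% of samples; bead count < 3 in ≥ 5% of samples; cross-hybridizing
probes; SNP-containing probes; and CpGs with no SNP within the cis
window (these could never yield a QTL record). The expression filter
drops probes whose detection p exceeds 0.05 in ≥ 95% of samples plus the
two exclusion lists.

Quantile normalization is implemented over arbitrary probe subsets —
one subset for expression, or the six Infinium probe-type subsets for
methylation intensities — replacing each sample's values by the mean
order statistics at their ranks, averaging reference values across tied
ranks, and interpolating the reference when samples differ in their
number of observed values (missing entries are excluded from ranking and
restored). The implementation is cross-checked against
`limma::normalizeQuantiles` in the tests. Raw expression signals are
log2-transformed after a +16 offset.

## Enrichment machinery

**Annotation enrichment.** meQTL-CpGs differ systematically from the
array background in their methylation level, and most annotation tracks
correlate with methylation level; comparing QTL-CpGs against unmatched
controls would therefore confound the two. Controls are matched on the
per-CpG **median** β (the mean is available by passing a different
matching statistic), binned into ten deciles with the final bin closed
at 1, sampling `match_ratio` controls per target without replacement
from a non-QTL pool (default ratio 7). One control set is drawn per
analysis and reused for all tracks. Enrichment per track is the exact
Fisher test: odds ratio by the cross-product, two-sided p by the
point-probability rule (sum of hypergeometric tables no more probable
than the observed one — verified against full enumeration for every
table up to n = 60), 95% CI by the log-OR normal approximation, 0.5
continuity correction (flagged) when a cell is zero, and Bonferroni
q-values over the number of tracks actually tested, not a hard-coded
family size.

**LD-overlap enrichment.** Both SNP sets are first reduced to
quasi-independent index SNPs by p-value-ordered clumping: repeatedly take
the most significant unassigned SNP (ties broken by smaller position) and
absorb all unassigned SNPs with r² ≥ 0.25 within the clump window.
r² is the squared Pearson correlation of dosage vectors (composite LD,
as computed on unphased genotypes), and the clump window is a parameter
because different comparisons conventionally use different spans —
250 kb for GWAS overlaps, 1 Mb for QTL-vs-QTL comparisons. The observed
statistic counts target index SNPs with at least one reference index SNP
at r² ≥ 0.25 within the overlap window (a SNP in both sets overlaps
itself). The null re-draws the target set `n_sets` times from the
clumped non-QTL pool (scan FDR > 10%), matching the target's MAF
histogram exactly in 0.02-wide bins; enrichment is observed/null-mean
and the empirical p is the fraction of null sets reaching the observed
count, reported as `< 1/n_sets` when none does (the add-one estimator is
available as an option). `n_sets` defaults to 10,000 — the estimator is
unchanged if a user restores a larger value. By default SNPs in a
configurable exclusion region on chromosome 6 (preset
chr6:2,500,000–3,500,000) are removed before counting; note the
extended-LD MHC region conventionally dropped in such analyses spans
roughly chr6:28–34 Mb on GRCh37, so callers matching a specific
published pipeline should set the interval they need rather than rely on
the preset.

**Prioritization.** CADD-Phred scores, TFBS-alteration predictions and
GWAS catalogs are consumed as plain TSV snapshots (no network access).
Records keep only SNPs scoring strictly above the threshold (default 5);
the best SNP per probe maximizes the score with ties broken by smaller p
then smaller position. CpG creation/abolition is evaluated on the
forward strand only — callers supply reverse-complemented context for
minus-strand sites — by testing the CG dinucleotide in (left + allele)
and (allele + right) for both alleles. The background for
transcription-factor over-representation defaults to the thresholded
records not in the best set; this choice is a package decision, and the
Fisher machinery is shared verbatim with the annotation engine.

## The synthetic cohort

The generator reproduces the structure the analysis assumes, at the
cohort scale it is designed for (defaults: 110 samples, MAF ∈
[0.05, 0.5]):

- **Genotypes**: LD blocks of 10 SNPs at fixed 2 kb spacing on one
  synthetic chromosome. Each block has one allele frequency; per sample a
  latent haplotype anchor pair is drawn and every SNP copies the anchor
  allele with probability c, else redraws at the block frequency, giving
  pairwise dosage r² = c⁴ — so c = target^(1/4) hits the requested LD
  exactly in expectation, and block membership gives exact control for
  overlap constructions. Columns whose empirical MAF leaves the range
  are redrawn. Block-copy LD was chosen over coalescent simulation
  precisely for this controllability; the price is no recombination
  gradient and no population structure.
- **Methylation**: per CpG a Gaussian liability (covariate effects +
  noise) mapped through the inverse logit with a per-class shift of
  −3/0/+3 for the unmethylated/intermediate/methylated mixture classes
  (weights 0.45/0.10/0.45), which makes background medians bimodal with
  modes near 0 and 1. Planted QTL-CpGs sit in the intermediate class —
  matching the observed intermediate methylation of QTL-CpGs — where the
  inverse logit is nearly linear; their liability is
  √v·g + covariates + orthogonalized noise completing unit variance,
  squashed by a factor 0.4 before the transform so rare-homozygote
  dosage levels stay out of the saturating tails. With that construction
  the realized β-scale genotype share tracks the requested fraction v to
  within ~0.02 across the MAF range, which is what makes ±0.05 parameter
  recovery a fair test. The logistic-liability noise model itself is a
  stand-in: no claim is made that real 450K noise looks like this.
- **Expression**: the same construction on a Gaussian log2 scale centred
  at 8, no transform. Shared-driver triples arise by planting the same
  SNP index for a CpG and a transcript.
- **Covariates**: gender Bernoulli(0.5), age uniform on [1, 67] years,
  neuronal proportion Beta(2,2) rescaled to [0.2, 0.8]; covariate
  effects default to 5%/3%/1% of probe variance with random signs.
- **Tracks and GWAS lists**: tracks cover each CpG with probability q
  (QTL) or p (background, default 0.15) with odds(q)/odds(p) equal to the
  planted enrichment odds, intervals ±100 bp around covered CpGs; GWAS
  lists place one hit per LD block, a chosen fraction in QTL-carrying
  blocks, p-values below 5 × 10⁻⁸.

All generators are pure functions of (config, seed): they restore the
caller's RNG state, and the pipeline derives per-stage seeds from the
master seed through fixed per-stage offsets, so inserting a stage never
perturbs another stage's draws and identical (config, seed) runs produce
byte-identical outputs and manifests.

What passing tests on this cohort do **not** show: robustness to
recombination gradients, population stratification beyond what planted
subpopulation constructions probe, array batch structure, probe-specific
noise, or cell-type interactions — real-data features the generator
deliberately omits.

## Numerical choices and degenerate inputs

- Window boundaries (cis window, clump window, overlap window, QC rule
  five) are all inclusive; region exclusion uses closed 1-based bounds.
- β deciles are left-closed, last bin closed at 1, with a 10⁻⁹ guard
  against decimal-times-ten floating error at bin edges.
- Fisher point-probability comparisons use a (1 + 10⁻⁷) relative guard;
  the exact-HWE comparison uses the analogous guard.
- Clumping and best-SNP ties break on smaller genomic position —
  determinism over elegance.
- Residual correlations are clipped to [−1, 1] before the t transform;
  1 − r² is floored at machine scale to keep exact fits finite.
- Degenerate inputs fail loudly before computation: sample misalignment
  aborts the scan, rank-deficient covariate designs name the collinear
  columns, empty QC output warns, monomorphic dosages and zero-variance
  residual vectors are skipped with logged counts, and matching
  shortfalls name the offending bin.
- The pipeline's desk-scale demo clamps the simulated GWAS list to the
  cohort's LD-block budget and widens the MAF bin deterministically when
  a bin cannot be matched; the core `maf_matched_sets` and
  `sample_matched_controls` operations never do this silently — they
  error.

## Open choices, resolved

- Hard-call dosages are the default genotype representation; fractional
  imputed dosages are accepted everywhere except the exact HWE test,
  which rounds to genotype classes.
- The bead-count rule is interpreted as bead count < 3 in ≥ 5% of
  samples.
- Control matching uses the median β; the matching statistic is supplied
  by the caller, so mean-matching is one argument away.
- The seven-fold control pool is drawn once per analysis and reused
  across tracks, not resampled per track.
- BH is applied separately per scan; whether enrichment pools should
  share a family with the scans is a question the package answers "no".

## Problem sizes

The shipped test and acceptance runs use: null-FDR calibration at 200
replicates of 110 samples × 500 SNPs × 200 CpGs; variance-fraction
recovery at 50 replicates of n = 2000; the Fisher sweep over all ~6 × 10⁵
tables with n ≤ 60; annotation recovery at 5,000 CpGs; LD-overlap
recovery at 1,500 SNPs with a 10,000-set empirical null; and the
end-to-end demo at 110 × 600 × 600. These sizes were chosen so each
statistical property is measured with comfortable Monte-Carlo margin
while the whole suite stays interactive.

## Known limitations

Single-chromosome synthetic genomes (multi-chromosome inputs are fully
supported in the readers and the engines, but the generator does not
emulate them); no trans-QTL scanning; no dominance or interaction
models; no surrogate-variable alternatives to the PC-based adjustment;
correlation, not mediation — the methylation–expression module makes no
directional causal claim.
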