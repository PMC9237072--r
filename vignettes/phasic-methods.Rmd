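---
title: "Methods: detecting cell-cycle phasic gene expression"
author: "phasic package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting cell-cycle phasic gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Most genes are expressed at a constant level across the cell cycle; a
*phasic* gene changes its mRNA abundance between phases. In DNA-content-sorted
material we observe two populations, G1 and G2/M, and ask per gene whether
abundance differs between them — in bulk RNA-seq of sorted pools, and in
droplet single-cell RNA-seq of sorted cells where dropout and per-cell capture
efficiency dominate the noise. Two further questions follow: whether a phasic
effect is *lineage-specific* (present in, say, endoderm but not in the
reference neuroepithelium), and whether phasic expression is driven by phasic
*transcription* or phasic transcript *stability*, which an exon/intron split
of total RNA-seq can separate because introns turn over rapidly and so track
transcription.

`phasic` implements this analysis family end to end, together with a negative
binomial simulator that plants known effects so every pipeline can be scored
against ground truth.

## Bulk pipeline

Genes are first filtered on expression: a gene is kept when its CPM exceeds 5
in every member of at least one replicate set (samples sharing stage and
phase), and its mean CPM across the tested samples exceeds 5. Samples are
normalized by trimmed mean of M-values (TMM): against a reference column
(upper-quartile proportion closest to the mean), per-gene log2 ratios of count
proportions are doubly trimmed (30% on M, 5% on A) and combined with
delta-method precision weights. We write the weights in terms of detection
proportions, `(1 - p_k)/p_k + (1 - p_r)/p_r`, with the depths cancelled: this
keeps the factors *exactly* invariant to rescaling any column, which the
textbook depth-dependent weights violate slightly. Factors are normalized to
product 1.

Differential expression between G1 and G2/M uses a per-gene negative binomial
log-linear model with `log(library x factor)` offsets and a Wald test of the
phase coefficient (reported as log2, G2M minus G1). Two aspects are tuned to
the reality of phase-sorted designs, which often have only 2–3 replicates per
phase:

* **Dispersion.** The per-gene dispersion is the method-of-moments total
  squared coefficient of variation of the fitted residuals,
  `phi = sum(((y - mu)/mu)^2)/(n - p)`, floored at 1e-8 and then at the
  across-gene median. With 4 residual degrees of freedom roughly half of all
  raw estimates underestimate badly, and those genes dominate the false
  calls; the median floor removes exactly that failure mode without fitting
  any trend or shrinkage across genes.
* **Weighting and reference distribution.** Counts passing the CPM filter are
  large enough that the NB working weight `mu/(1 + phi mu)` is essentially
  constant, so the score is solved in that dispersion-dominated regime
  (`sum x (y - mu)/mu = 0`). A side benefit is exact depth equivariance:
  every inferential quantity depends on count proportions only, so the call
  set is unchanged when all counts are rescaled globally — a property that no
  depth-aware dispersion estimate can deliver. The Wald statistic is referred
  to a t distribution on `residual df + 20`, crediting the median floor with
  prior information in the spirit of moderated statistics; with many
  replicates this approaches the chi-squared limit. At the study's design
  sizes this calibrates the type-I error at 0.05 to ~0.03–0.05 for both
  n = 3 + 3 and n = 10 + 10.

P-values are Benjamini–Hochberg adjusted (our own step-up implementation,
`bh_adjust`) and genes called phasic at adjusted p below `alpha_bulk` (0.1).

### Exon/intron decomposition

Intronic abundance is proportional to transcription; exonic abundance to
transcription times stability. Three empirical-Bayes moderated t tests of
phase are run on log2(CPM + 1): exon (expression), intron (transcription),
and the per-sample exon-minus-intron difference (stability, pseudocount 1
guarding zeros). The moderated t follows the standard scaled-F moment-matching
construction: `d0` is recovered from the excess log-variance spread through a
trigamma inversion (Newton with a bisection fallback; no finite root means
full pooling), posterior variances are `(d0 s0^2 + d s^2)/(d0 + d)`, and the
statistic has `d + d0` degrees of freedom.

The expression test is BH-adjusted over all filtered genes; the two component
tests over the *classification family* — expression-phasic genes with
adequate intronic coverage (intron CPM above 5 across one replicate set) —
because that is the population in which the decision is made, and adjusting
them over all ~2000 genes leaves most true drivers unresolved at the study's
effect sizes. Classification among that family:

* both components significant (adjusted p < `alpha`): **BOTH**;
* one significant, the other showing *no trend at all* (adjusted p >= 0.5):
  **TRANSCRIPTION** or **STABILITY**;
* anything in between — one significant and one intermediate, or neither
  significant — **UNRESOLVED**; genes without intronic coverage are likewise
  UNRESOLVED, and non-phasic genes NOT_PHASIC.

The indeterminacy band (0.1 <= p < 0.5) is deliberate: a pure-driver call
asserts the *absence* of the other mechanism, and with three replicates the
absence of significance is weak evidence of absence. Setting `ambiguity_p =
alpha` disables the band and recovers a plain significant/not-significant
rule.

## Single-cell pipeline

Cells pass three QC rules in order: at least 5000 UMI; below 5% mitochondrial
reads (genes with the `mt-` prefix by default); and at least 40% of the genes
detected by the most gene-rich surviving cell. Genes detected in fewer than
20% of cells are removed.

Because droplet capture is inefficient (~10%), inference runs on *pseudobulk*:
within each phase (and lineage, when present) cells are shuffled and summed
in disjoint blocks of 10; leftover cells are dropped for that draw and
re-enter on the next randomization. Counts are conserved exactly: per gene,
pseudobulk totals plus dropped-cell counts equal the input totals.

Per gene the two-part **hurdle model** is fitted on log2(CPM + 1) of the
pseudobulk samples: a logistic regression of the detection indicator
(expression > 0) and a Gaussian regression of abundance among detected units,
under `~ cell_cycle_phase + fraction_of_detected_genes` (the detection
fraction of the pseudobulk unit relative to the best unit — a capture
efficiency proxy). Terms are tested by likelihood ratio, summing the two
components' statistics and degrees of freedom (rank deficits of the deleted
columns, per live component). Numerical choices:

* the discrete component carries a ridge of 1e-6, keeping the likelihood
  finite under perfect separation while perturbing coefficients by less than
  1e-6 otherwise;
* the continuous component is dropped when detected units number at most
  coefficients + 1, the discrete one when detection is all-or-none; a gene
  with neither component is untestable (`NA`, excluded from the BH family);
* residual variances are floored at 1e-8 so perfect fits stay finite;
* the continuous likelihood-ratio statistic is **calibrated through its exact
  finite-sample F distribution** and mapped back to the equivalent
  chi-squared quantile before the components are summed. At 60 pseudobulk
  units the naive chi-squared reference is visibly liberal (null tail ~0.059
  at 0.05) and a 2000-gene uniformity test detects it; the F-calibration
  restores per-gene exactness for the all-detected case, which dominates
  pseudobulk data.

The **permutation-median caller** re-randomizes the pseudobulk blocks 100
times; within each permutation the hurdle p-values are BH-adjusted, and each
gene receives the median adjusted p across permutations ("median FDR"), with
missing permutations excluded unless they exceed half, in which case the gene
is uncalled. A gene is phasic when its median adjusted p is below `alpha`
*and* its median phase difference of mean log2(CPM + 1) exceeds log2(1.1) in
absolute value. The fold-change threshold of 1.1 is read as a ratio (the gate
is ~0.138 log2 units), since 1.1 is idiomatic as a fold change; the
alternative reading (1.1 log2 units) is available by setting `fc_threshold =
2^1.1`. The gate is applied after the p-threshold and can only remove calls.

**Lineage interactions** extend the design to `~ phase + lineage +
phase:lineage + detection` with treatment coding against a reference lineage.
Cells are first down-sampled so both phases contribute equally within each
lineage. Each non-reference lineage's interaction column is deleted
individually (per-lineage contrasts, the default report; the whole-block test
is also exposed), BH-adjusted across genes within the lineage, and
median-summarized over permutations as above, gated on the interaction-scale
fold change. The **scrambled-lineage control** rebuilds pseudobulk from
same-phase cells of mixed lineages while keeping the per-(phase, lineage)
sample counts of the matched construction, so both arms have identical
statistical power; lineage-linked signal must vanish there.

**Genotype comparisons** draw, for each of 100 resamples, the same number of
cells per phase from each genotype (the common minimum), run one pseudobulk
hurdle pass per genotype, and take per-gene medians of the adjusted p across
resamples; each resample uses one derived seed shared by both genotypes, so
an identical mutant reproduces the control's calls exactly. Calls use median
adjusted p < 0.1 with the fold-change gate.

**Clustering check.** As a structural readout, 2-means clustering of cells on
log2(CPM + 1) over a phasic gene set is scored by the fraction of cells whose
cluster matches their DNA-content phase (best of the two label mappings).

## Co-expression in unsorted populations

The canonical G1/S (9 genes) and G2/M (15 genes) transition panels are
shipped as a TSV resource. In an unsorted population, 50-cell cohorts are
drawn without replacement within stage and group, pairwise Pearson
correlations of log2(CPM + 1) are computed over the panel genes
(zero-variance genes excluded and flagged), and the mean off-diagonal
correlation within each panel and between panels summarizes the phasic
structure; 20 cohorts per stage by default (the count is not fixed by any
external constraint and is exposed as an argument). With phasic structure the
within-panel means are positive and the between-panel mean negative; the
summaries are invariant to per-cell library rescaling.

Per-cell activity scores (e.g. regulon activities computed elsewhere) are
compared between phases with a two-sided two-sample Kolmogorov–Smirnov test;
an activity is phase-specific below p = 1e-12. With very few cells the
discrete p-value floor makes that threshold unreachable regardless of
separation — by design.

## The synthetic-data generator

`simulate_sc` draws gene baselines log-normal(0, 1), per-cell library sizes
log-normal with median ~8000 UMI (so the 5000-UMI QC floor is exercised but
healthy cells sit above it), and counts NB with dispersion 0.2
(variance = mu + phi mu^2); dropout arises from low means, not from a
separate zero-inflation process. Phase effects are multiplicative and split
symmetrically (G1 x 2^(-beta/2), G2M x 2^(+beta/2)) so a phasic gene's
phase-averaged expression stays constant while the differential grows.
Lineage baselines are log2-normal with sd 0.25 in non-reference lineages;
lineage-specific effects restrict beta to one designated lineage.
Mitochondrial genes (prefix `mt-`, 1% of genes, 2% of expression) let the QC
rules engage without configuration; planted low-quality cells (4% in the
presets) have library sizes around 2000 UMI or ~20% mitochondrial load, far
enough from the thresholds that they are removed almost surely — a healthy
cell can still straddle a threshold stochastically, which the tests allow
for. `simulate_bulk_exon_intron` plants transcription and stability factors
(intron mean proportional to T, exon to T x S, intronic libraries 30% of
exonic, dispersion 0.05, three replicates per phase). `simulate_activity_scores`
draws Gaussian scores with a G2M mean shift.

What the generator does **not** emulate: batch effects, gene length, ambient
RNA, doublets, realistic lineage proportions, mean-dispersion trends, or
gene–gene correlation beyond the phase latent. Passing tests therefore show
the inference machinery is correct and calibrated under the stated model —
not that real embryo data would behave identically.

The preset study conditions (also used by `scripts/acceptance.R` and the
acceptance tests): `sc-null` 2000 genes x 300 cells/phase with no effects;
`sc-phasic` 2000 x 500 with 10% of genes at |log2FC| = 1; `sc-interaction`
three lineages x 150 cells/phase with 5% of genes at |log2FC| = 1.5 restricted
to endoderm; `genotype-pair` 250 cells/phase per genotype with 100 vs 150
planted genes; `bulk-decomp` 2000 genes, 50/50/20
transcription/stability/both drivers at 1 log2 unit, n = 3 per phase. These
sizes keep a full run of the test suite and the acceptance script within a
few minutes on one core while leaving all the operating-point margins wide.

## Known limitations

* The hurdle discrete component wastes a degree of freedom when detection is
  nearly complete (1–2 zeros in 60 units), making those genes mildly
  conservative; the permutation median masks this in calls but it is visible
  in pooled raw-p uniformity checks.
* The bulk Wald test's exact depth equivariance is bought by the
  dispersion-dominated weighting; for genes barely passing the 5-CPM filter
  in shallow libraries the constant-weight approximation is at its weakest.
* Gene-wise dispersion with a median floor and no trend is deliberately
  simple; datasets with a strong mean-dispersion trend would benefit from a
  trended estimator, which is out of scope here.
* The decomposition's indeterminacy band trades recall of pure drivers for
  precision among resolved calls; analyses that prefer the plain rule can set
  `ambiguity_p = alpha`.
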