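---
title: "Methods: composite z-score pathway biomarkers in a paired surgery cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite z-score pathway biomarkers in a paired surgery cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deptx)
```

## The design deptx models

`deptx` analyzes a paired pre/post intervention cohort: obese patients with
and without major depressive disorder (MDD), whole-blood expression profiled
at baseline and again after bariatric surgery, with depression severity
quantified by the MADRS clinician rating (points, 0–60). Surgery resolves
both the systemic inflammation of obesity and, in most patients, the
depressive symptoms — so a transcriptional pathway that is elevated in MDD
at baseline *and* normalizes after surgery, in proportion to symptom
improvement, is a candidate biomarker of inflammation-related depression.

The package's statistic for one pathway is the **composite z-score**: genes
are standardized over the study population, `z = (x − μ)/σ` with σ the
*population* SD (divisor *n* — a deliberate convention, since the cohort is
treated as the population of interest, not a sample from one), and the
pathway score of a transcription factor is the unweighted mean of its
expressed target genes' z-scores. Unweighted because target lists come from
ChIP-seq-derived collections (GMT format) that carry no calibrated edge
confidence; weighting would import noise dressed as information.

## Stages, parameters, and defaults

**Preprocessing.** Expression is assumed log2-scale. Quantile normalization
(`quantile_normalize`) forces a common distribution of order statistics
across samples, with within-sample ties receiving the mean of their assigned
quantile values; it is idempotent. The expression filter keeps genes with
median ≥ `min_median` (default 1.0 log2 units) and SD strictly greater than
`min_sd` (default 0): the strict inequality guarantees no zero-variance gene
can reach z-scoring, where σ = 0 would be undefined. The survivors define
the *expressed universe* used both as the enrichment background and as the
target-gene filter for composites — one consistent notion of "expressed in
this data set". Correlated latent structure (batch, cell-composition drift)
can be reduced with `remove_latent_factors(k)`: the matrix is centered on
group × timepoint cell means so condition signal is protected, the top *k*
principal components of the residual are subtracted, and the means restored.
This is a transparent PCA residualization, simpler than a full
factor-analytic multiple-testing model; it shares that model's goal
(weakening the gene dependence structure before inference) with mechanics
that are easy to verify — a rank-1 artifact orthogonal to the conditions is
removed essentially exactly, and gene variances can only decrease.

**Sparse PLS selection.** `fit_spls` implements regression-mode sparse PLS:
per component the X-loading is the soft-thresholded covariance `X'y` on
standardized data, renormalized to unit length, with the threshold set by
order statistic so exactly `keep_x` loadings are nonzero; X is deflated by
its own scores, y is never deflated. One component is the default because
the stage is used for *selection* (which genes track MADRS), not
prediction; `keep_x` defaults to 2000, the scale at which a microarray
selection of this kind is usually cut before pathway analysis, and
`threshold_by_r` then applies the conventional |r| > 0.5 "highly
correlated" cut, splitting by sign. Determinism is enforced twice: ties at
the soft-threshold boundary are broken lexicographically by gene ID (an
exactly tied gene is kept in the support with an infinitesimal weight, an
event of measure zero on real data), and the sign is fixed so the
largest-magnitude loading is positive. With no thresholding the loading is
proportional to the vector of gene–response correlations, which is the
property the test suite pins against a brute-force |covariance| ranking.

**Differential expression.** Three contrasts: MDD vs non-MDD at baseline
(Welch t by default — group variances have no reason to be equal), and post
vs baseline within each group as a one-sample t on within-patient
differences, which is the blocking-on-patient analysis in its simplest
exact form. Patients lost to follow-up are excluded from paired contrasts
and counted (`n_excluded`). An optional `"moderated"` mode shrinks per-gene
variances toward an inverse-chisquare prior fitted by moments from the log
sample variances (a trigamma inversion), adding the prior df — useful at
small n; the mode used is recorded on the result. Two-sided p-values
throughout; genes with zero spread are reported as t = 0, p = 1 and
flagged, never dropped silently. FDR control is Benjamini–Hochberg at
0.05.

**Upstream regulators.** With no access to a curated causal knowledge base,
the package scores user-supplied target sets openly: overlap between the DE
list and a regulator's targets (both restricted to the expressed universe)
is tested with the exact hypergeometric upper tail, and direction
consistency is summarized by `z = (n_consistent − n_inconsistent)/√N` over
the overlapping targets with a known expected direction (carried as `+`/`−`
suffixes in the GMT, since activation direction is a property of the
regulator–target edge, not of the set). Undirectioned targets count toward
overlap but not toward z. Across regulators, BH is applied within each
contrast and reported next to the conventional raw cutoff p < 0.001.
`compare_contrasts` lays the per-contrast z-scores side by side, sorted by
maximum |z| — the view used to ask which regulators change after surgery in
depressed but not in non-depressed patients.

**Transcript origin analysis.** A gene's diagnosticity for a cell type is
its reference expression minus its mean across cell types (log2 units; rows
sum to zero, so the analysis is invariant to adding any constant to the
reference). The test statistic is the mean diagnosticity of the DE list;
the null resamples equal-sized lists *without replacement* from all scored
genes — matching "a random gene list of the same size" exactly, rather than
approximately as with-replacement sampling would. The Monte-Carlo p uses +1
smoothing and counts null values exactly equal to the observed statistic
with weight one half; without the half-weight, the degenerate case where
the DE list is the entire scored universe (every resample ties the observed
mean) would report p = 1 when p ≈ 0.5 is the honest answer. One-sided,
overrepresentation only. `n_boot` defaults to 2000, placing the resolution
floor at p ≈ 5 × 10⁻⁴, well below the table-wide BH threshold.

**Validation.** The two-way group × surgery ANOVA uses Type II sums of
squares: the post-dropout design is unbalanced, and Type II is the
conventional default when the hypotheses of interest are the classical main
effects and interaction (Type III is available via `type = 3`). Timepoint
is treated as an ordinary between-cell factor; the composite's
patient-level component is small by construction (per-gene patient offsets
average out across a target set), so a repeated-measures model buys little
here. Post hoc, the four contrasts of scientific interest — MDD vs non-MDD
within each timepoint, post vs baseline within each group — are tested
against the pooled MSE with Bonferroni multiplication by exactly 4.
Regressions report the coefficient on standardized variables (`beta_std`,
equal to the Pearson correlation in the crude model, with F = t²), so
slopes are comparable across pathways; the remission regression uses
baseline-minus-post on both sides, so positive slopes mean "biomarker drop
predicts symptom drop". Covariates are never imputed: a requested covariate
with missing values is a hard error.

## What the synthetic cohort emulates — and what it does not

`simulation_config()` defaults encode the emulated study's conditions: 33
patients, 15/33 MDD, 9 lost to follow-up (stratified by group, giving the
4/5 split), and MADRS drawn per group × timepoint with means/SDs 19.00 ±
3.87 (MDD baseline), 6.56 ± 3.59 (non-MDD baseline), 6.36 ± 5.09 (MDD
post), 2.08 ± 3.29 (non-MDD post), truncated at 0 by inverse-CDF sampling
(MADRS is a non-negative score; the post-surgery SDs would otherwise
produce negatives, and rejection-free truncation keeps the random stream
length deterministic).

The expression layer: each regulator *r* has a latent activation per sample,
`a_r = α_r · zMADRS + N(0,1)`, with zMADRS standardized over all simulated
samples; post-surgery latents are re-drawn from the post-surgery MADRS, so
clinical remission propagates into the transcriptome by construction.
Target genes load positively on their regulator's latent (`b_g` uniform on
0.3–0.7 log2 units per latent unit — chosen so a single target's z-score
correlates ≈ 0.6–0.8 with its latent at the default noise, i.e., targets
are informative but individually noisy, which is what makes averaging into
a composite worthwhile), non-targets are baseline plus noise, and every
patient keeps per-gene baseline offsets (SD 0.3 log2 units) across
timepoints so pairing is informative. `α` defaults to 1.5 z-units per MADRS
SD, a coupling chosen for test power rather than biological realism — the
study this emulates reports no effect sizes on the expression scale. One
seed drives everything; the cell-type reference uses a fixed offset of that
seed so cohort and reference are independently reproducible.

Not emulated: microarray noise physics (dye bias, spatial artifacts, probe
saturation), the batch covariates of a real hybridization series, cytokine
measurements, and any direct MDD-diagnosis label post-surgery (remission is
expressed through MADRS). Passing tests on this generator therefore shows
that the *statistical machinery* is correct and calibrated under the
declared generative model — not that the pipeline will recover biology from
any particular real data set.

## Calibration and power under the default conditions

The test suite measures, at fixed seeds:

* **Type I**: with α = 0 the composite–MADRS regression rejects at ≈ the
  nominal 5% (bounded at 7% over 200 replicates), and the DE stage's
  empirical FDR at the 0.05 threshold stays below 0.075 across 200 null
  cohorts.
* **Recovery**: with α = 1.5 the causal regulator's composite correlates
  with MADRS at median r ≈ 0.8 (> 0.5 across 20 replicates), and the
  remission delta regression detects the coupling in well over 80% of
  replicates at 24 pairs.
* **A known power limit**: the group × surgery interaction at p < 0.01
  succeeds in only about half of replicates at the default coupling and
  cohort size. This ceiling is inherent to the generative model, not to the
  estimator: the unit-variance latent noise and the MADRS cell means fix
  the interaction noncentrality near t ≈ 2.7 (scoring the *true* latent
  activation gives the same rate), so no analysis of the composite can do
  materially better. Interaction claims at this cohort size should be read
  with that in mind.

Monte-Carlo test sizes (gene panels of 150–500 genes, 20–200 replicates)
are scaled-down choices: the calibration quantities they estimate do not
depend on panel size beyond resolution, and the generator's cohort-level
conditions are never reduced.

## Degenerate inputs and numerical conventions

Zero-variance responses, empty universes, empty DE lists, regulators with
no expressed target, single-sample normalization, k ≥ n factor removal, and
post-surgery samples without a baseline partner are all hard errors with
named offenders. All-zero paired differences and identical groups report
t = 0, p = 1 with a degenerate flag. Composite invariants (per-gene z mean
0 and population SD 1; cohort mean of every composite 0) hold to 10⁻⁹ and
are asserted at that tolerance. Direction ties at log2FC = 0 resolve by the
t sign. BH is the standard step-up; Bonferroni p-values are capped at 1.

## Open choices made here

Three ambiguities had no authoritative answer and were decided once:
multi-probe genes are mean-collapsed at read time (making gene-set
membership well-defined); composites standardize over *all* analyzed
samples jointly by default (pre and post scores must share a scale for any
pre/post comparison to mean anything), with `cohort = "baseline-only"`
available; and diagnosticity is the centered difference rather than a ratio
(log-scale expression makes differences the natural contrast). Each is a
package convention, stated here so downstream users do not mistake it for a
property of the data.
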