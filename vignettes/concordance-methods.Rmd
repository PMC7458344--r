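---
title: "Methods: deconvolution-IHC concordance, permutation significance, and infiltration signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deconvolution-IHC concordance, permutation significance, and infiltration signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoconcord)
```

## The problem

Quantitative immunohistochemistry reports marker-positive cell densities
(cells/mm² of tumor tissue) for a handful of markers — here CD3 (all T
cells), CD8 (cytotoxic T cells) and CD68 (macrophages). Bulk RNA-seq
deconvolution reports scores for dozens of finer cell types. In poorly
infiltrated tumors such as pancreatic adenocarcinoma the transcripts
contributed by rare immune cells approach the detection limit of
deconvolution, so scores collapse to zero even for patients with
histologically confirmed infiltrates. This package implements the analysis
layer for quantifying that disagreement and for working around it with an
expression signature of infiltration.

## Composite scores

An IHC marker's deconvolution equivalent is the aggregate of all cell types
that express it. `build_composites()` applies a rule (default `sum`) over
the constituent rows of a deconvolution matrix. Sum is the default because
combined groups of cell abundances are additive in cell counts; a mean
would shrink composites that contain many rare subtypes. The rule is
configurable because aggregation of *enrichment*-type scores is a
convention, not a physical sum.

The built-in mappings (`default_mapping()`) cover the LM22 CIBERSORT
catalog (CD3 = 7 T-cell subsets, CD8 = the single CD8 row, CD68 = three
macrophage states) and the 64-type xCell catalog (CD3 = 14 T-cell subsets
including NKT, CD8 = 4, CD68 = 3). Whether NKT belongs under CD3 is
genuinely ambiguous — NKT cells express CD3 but are often tabulated apart
from conventional T cells; we include it and let users override by
constructing a `composite_mapping()` with their own lists. Cell-type name
matching is exact after trimming surrounding whitespace, and aggregation is
strict by default: a missing constituent is an error, because a silently
partial composite would corrupt every downstream concordance number.
Lenient mode (`strict = FALSE`) logs and drops absentees, for tool exports
that omit all-zero rows.

## Permutation significance of concordance

Spearman rank correlation (average ranks at ties, pairwise-complete, at
least three complete pairs) measures composite-IHC agreement. Its
significance is assessed against a cell-type permutation null: each
permutation draws a random constituent set of the *same cardinality* as the
true set, uniformly without replacement from the method's full catalog,
rebuilds the composite and recomputes rho. Cardinality is the only
preserved property, so a draw can coincide with the true set; we do not
exclude it, since the null being sampled is "a same-sized set chosen with
no biological knowledge". Draws for different markers are independent —
the true mappings themselves overlap (CD8 is a subset of CD3), so a
disjoint-partition constraint would be incoherent.

The empirical p-value uses the add-one rule
`p = (1 + #{rho_perm >= rho_obs}) / (n_perm + 1)`, one-sided in the
concordant direction. With the small permutation counts that catalog size
suggests (20 for 22 types, 100 for 64 — the package defaults), a plain
rank p could be exactly zero; the add-one form keeps p in (0, 1] and makes
the 19-below-observed boundary case exactly 0.05. One-sided is the right
shape for the scientific question (is the true assembly *better* than
random?); users wanting two-sided inference can double manually.

`percent_match()` quantifies gene-sharing between signature sets as
`100 * |A ∩ B| / |A|` — referenced to the row set's own size, hence
asymmetric, which is the natural reading of "what fraction of A's genes
recur in B". A symmetric Jaccard variant is a flag.

## Survival conventions

`stratify()` labels a patient "high" only when the value is *strictly*
greater than the cutoff, so cutoff ties land in "low"; this is unambiguous
and documented rather than universal — flip by pre-negating values if
needed. Percentiles use linear interpolation between order statistics
(R's default type-7 quantile), one fixed convention among the many
percentile dialects. Kaplan–Meier estimation and the log-rank test
(hypergeometric variance with tie correction, 1 df) are delegated to the
`survival` package and cross-checked in the test suite against hand-rolled
product-limit and observed-minus-expected oracles. The two-factor analysis
(`two_factor_survival()`) reports each within-stratum comparison
individually, without multiplicity correction, matching how such
subgroup splits are conventionally read; the output notes skipped strata.

## Signature discovery

HI patients are above both the CD3 and CD8 cutoffs (defaults: CD3 at the
75th percentile, CD8 at the median); LOW patients are below both;
discordant or incomplete patients are excluded. Per-gene differential
expression between HI and LOW uses a two-sided two-sample t-test with a
stringent unadjusted threshold (α = 0.001) as the false-positive control.
The pooled (equal-variance) variant is the default: recomputing the
packaged 38-gene discovery table with the pooled test reproduces the
published per-gene p-values to within a few percent (IL7R ≈ 3.7e-6),
while Welch departs noticeably; Welch remains available as a flag. A
Benjamini–Hochberg FDR column is emitted for reference only.

The packaged fixture stores the published expression values verbatim at
their printed two-decimal precision, and the tests operate on them
directly — so no assumption about the upstream normalization or log base
is needed. That rounding has one visible consequence: the gene nearest the
threshold (PPP1R16B, recomputed p = 1.003e-3) falls a rounding-width above
α, so 37 of 38 genes reselect.

## Enrichment classification

A validation sample is *enriched* for the signature when at least one
signature gene is overexpressed beyond a threshold. The default reading is
a z-score of 2 against a reference distribution (`zscore_vs_reference()`,
sample standard deviation, matching expression-portal practice); the
literal "two log-fold over the reference mean" reading is available by
passing log-ratios and `scale = "log_ratio"`. Lacking copy-number calls,
the default reference is all samples — an explicit approximation of the
diploid-reference convention, stated here rather than hidden. The
classifier is monotone by construction: raising any signature gene's score
can only preserve or create an enrichment call.

## Matrix preprocessing, clustering, PCA

Missing entries are completed by iterative truncated-SVD imputation:
initialize missing cells at row means, alternately reconstruct at fixed
rank and overwrite only the missing cells, until the largest change in an
imputed entry drops below `tol`. Defaults — rank `min(dim) − 1` capped at
10, `tol = 1e-6`, `max_iter = 100` — follow common SVD-imputation practice;
the rank used by the original heatmap tooling is unpublished, so results
that depend on it are treated as qualitative. Observed entries are never
altered, and non-convergence returns the current estimate with a warning
rather than failing.

Hierarchical clustering supports the distance/linkage combinations used in
infiltrate heatmaps (Manhattan or Euclidean distance, complete or average
linkage, correlation distance defined as 1 − Pearson r). Agglomeration is
delegated to `stats::hclust` and verified against a brute-force
agglomerative oracle on small instances; tie handling therefore follows
`hclust`'s deterministic ordering. PCA operates on unit-variance-scaled
rows after imputation; prediction ellipses place a new observation from
the same (assumed bivariate normal) group inside with the stated
probability, via the chi-square(2) quantile scaling of the group
covariance.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes, with defaults chosen once as order-of-magnitude descriptions of a
resectable pancreatic cancer cohort — they are *not* estimates of any real
cohort, whose per-patient density distributions are unpublished:

* 39 patients; latent log-normal CD3 density with median 300 cells/mm² and
  log-sd 1; CD8 latent mean shifted down by log 2 (cytotoxic cells are a
  subset of T cells) and CD68 sharing CD3's scale — the configuration
  exposes one location/scale pair and derives the others, keeping the
  parameter surface small.
* Latent correlations: CD3-CD8 of 0.8 (tightly coupled lineages), CD3-CD68
  of 0.2 (weak, as macrophage and T-cell infiltration track poorly). The
  CD8-CD68 entry is their product, i.e. macrophages couple to cytotoxic
  cells only through total T-cell infiltration; this keeps the implied
  3×3 correlation matrix positive semi-definite for all legal inputs.
* Observed IHC = latent density × log-normal noise (sd 0.2).
* Deconvolution scores: each marker's latent density is partitioned across
  its constituent subtypes by a single Dirichlet(1) draw per cohort, so the
  sum-rule composite recovers the latent density *exactly* in the no-dropout
  limit — making aggregation invertible and testable. Bystander catalog
  types get independent log-normal scores. Every score is then zeroed with
  probability `1 / (1 + score / dropout_scale)` — logistic in
  `log(score / dropout_scale)` — reproducing the zero-inflation that
  deconvolution shows below its detection floor (default floor 20
  cells/mm²) without committing to a mechanistic model.
* Expression: i.i.d. normal baseline log2-TPM (mean 3, sd 1); planted
  signature genes gain `effect_size` (default 2) log2 units per
  standardized unit of latent CD3. TPM is `2^log2x − 1` floored at zero,
  so `log2(TPM + 1)` returns the generated log values exactly except in
  the floored left tail.
* Survival: exponential with hazard `0.02 × exp(−0.5 z_CD3)` per month and
  an independent exponential censoring clock (rate 0.01) — the simplest
  hazard model with the monotone infiltration-protects property; censoring
  is non-informative by assumption.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: compositional competition between cell
fractions (scores are not constrained to sum to one), FFPE degradation and
batch structure, gene-gene correlation beyond the planted infiltration
axis, non-proportional hazards, and informative censoring. The generator
validates the machinery, not the biology.

## Problem sizes in the checks

The calibration and recovery checks run at sizes chosen to give stable
rates while staying quick to re-run: 200 null cohorts of 39 patients for
permutation-test calibration (expected rejection near 1/21 with 20
permutations), 500 replicates for log-rank size, 60 patients × 1000 genes
(40 planted) for signature recovery, and 500 patients at low noise for
composite concordance. Determinism everywhere comes from a single seed
argument; the generator is bit-reproducible for identical configurations.

## Known limitations

* The permutation test's null is "random same-sized cell-type set", not
  "no correlation"; a marker whose constituents dominate the catalog will
  have permuted sets that overlap the true set heavily, flattening power.
* The enrichment classifier's all-samples reference inflates the reference
  variance when many samples are truly enriched, making calls
  conservative.
* With 20 permutations the p-value grid is coarse (multiples of 1/21);
  catalogs of this size cannot produce p below 0.047.
* The t-test operates on whatever log-scale values are supplied; it does
  not renormalize, by design, so upstream normalization choices flow
  through untouched.
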