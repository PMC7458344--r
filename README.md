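# immunoconcord

Pancreatic adenocarcinoma is poorly infiltrated by immune cells, yet the
density of tumor-infiltrating T cells measured by quantitative
immunohistochemistry (IHC) predicts patient outcome. Gene-expression-based
deconvolution (CIBERSORT-style abundance, xCell-style enrichment) promises
the same information from a single RNA-seq run — but in T-cell-poor tumors
the few transcripts contributed by rare infiltrating cells push these tools
to their detection floor, producing zero scores for patients with
histologically visible infiltrates.

`immunoconcord` packages the analysis toolkit for asking how well the two
modalities agree, and for building an expression signature of T-cell
infiltration when direct deconvolution struggles:

* **IHC-equivalent composites.** Deconvolution reports fine-grained subsets;
  IHC counts marker-positive cells. A composite score aggregates the cell
  types expressing a marker, e.g. for CD3
  `C_CD3(s) = Σ_{k ∈ K_CD3} d_ks`, where `d_ks` is cell type *k*'s score in
  sample *s* and `K_CD3` is every CD3-expressing subset (all CD4 and CD8
  populations, Tregs, γδ T cells). Built-in mappings cover CIBERSORT/LM22
  and the 64-type xCell catalog.
* **Permutation concordance test.** Is the true mapping better than chance?
  The observed Spearman ρ between composite and IHC density is ranked
  against composites assembled from random cell-type sets of the same
  cardinality drawn from the method's catalog, with the add-one empirical
  p-value `p = (1 + #{ρ_perm ≥ ρ_obs}) / (n_perm + 1)`.
* **Survival stratification.** Median/percentile cutoffs (strict `>` defines
  "high"), Kaplan–Meier curves, log-rank tests, and a two-factor analysis
  (does macrophage infiltration refine T-cell outcome groups?).
* **Signature discovery and validation.** Patients double-high for CD3 and
  CD8 by IHC versus double-low define HI/LOW classes; a per-gene pooled
  two-sample t-test at the stringent α = 0.001 selects the signature. A
  validation cohort sample is called *enriched* when at least one signature
  gene has expression z ≥ 2 against the reference distribution.
* **Synthetic cohorts with ground truth.** `simulate_cohort()` generates
  correlated latent CD3/CD8/CD68 densities, noisy IHC readouts,
  Dirichlet-partitioned deconvolution scores with logistic dropout below a
  detection floor, planted infiltration-responsive genes, and exponential
  survival whose hazard falls with T-cell infiltration — so every pipeline
  stage can be tested against known truth.
* Matrix utilities in the conventions of expression heatmap tools:
  iterative SVD imputation, Manhattan/correlation-distance hierarchical
  clustering, PCA with 95% prediction ellipses.

A packaged fixture (`load_tcell_fixture()`) carries the published
normalized log expression of 38 infiltration-associated genes across 28
patients (15 HI, 13 LOW) and anchors the signature pipeline end to end.

## Worked example

```r
library(immunoconcord)

# Signature discovery on the packaged discovery cohort
fx  <- load_tcell_fixture()
sig <- ttest_per_gene(fx$expr, fx$classes, variant = "pooled", alpha = 0.001)
print(sig, n = 5)
#> gene_signature: 38 genes tested (pooled t-test, 15 HI vs 13 LOW), 37 selected at p < 0.001
#>     gene  mean_diff        t            p direction selected
#>     IL7R 23.7364615 5.839839 3.724820e-06  up_in_HI     TRUE
#>   TESPA1  1.2751282 5.722959 5.045574e-06  up_in_HI     TRUE
#>   SLAMF1  0.9614872 5.487207 9.334302e-06  up_in_HI     TRUE
#>  KATNAL2  0.6777949 5.449565 1.030115e-05  up_in_HI     TRUE
#>    BFSP2  2.5057949 5.183866 2.069891e-05  up_in_HI     TRUE
```

The IL7R p-value (3.7e-06) matches the published analysis of these data;
37 of the 38 genes clear α = 0.001 when recomputed from the stored
two-decimal values (the one miss, PPP1R16B, sits at p = 1.003e-3, a
rounding-level distance from the threshold).

```r
# Concordance of a CD3 composite with IHC on a synthetic cohort
co   <- simulate_cohort(sim_config(n_patients = 100, seed = 7))
pr   <- permutation_significance(co$decon$cibersort_lm22,
                                 setNames(co$ihc$cd3, co$ihc$patient),
                                 default_mapping("cibersort_lm22"),
                                 "CD3", seed = 3)
print(pr)
#> Composite concordance permutation test, marker CD3
#>   observed Spearman rho = 0.933 over 100 complete pairs
#>   20 random same-size cell-type sets: empirical p = 0.04762
```

With 20 permutations the smallest attainable p is 1/21 ≈ 0.048: the true
cell-type assembly beats every random one.

```r
# Survival split by the composite, strong protective infiltration
co2  <- simulate_cohort(sim_config(n_patients = 200, hazard_log_ratio = -1.5, seed = 7))
comp <- build_composites(co2$decon$cibersort_lm22, default_mapping("cibersort_lm22"))
survival_by_cutoff(co2$ihc$time, co2$ihc$event, comp["CD3", ], strat_rule("median"))
#> high/low survival comparison at cutoff 261.1
#>   n = 100 high, 100 low; log-rank chisq = 99.375, p = 2.09e-23
```

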