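---
title: "Benchmarking missing-value imputation for quantitative proteomics"
author: "ImputeBenchMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking missing-value imputation for quantitative proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ImputeBenchMS)
```

## The problem

Label-free quantification matrices from bottom-up proteomics -- peptide
precursors, phosphopeptides or proteins in rows, biological samples in
columns -- are riddled with missing cells. Missingness is a mixture of
mechanisms: cells missing completely at random (MCAR, e.g. stochastic
sampling of precursors), and cells missing not at random (MNAR), which in
mass spectrometry means left-censoring of low-intensity signals below the
detection limit. Which imputation algorithm to use is not a settled
question, and the answer depends on the dataset; the defensible approach
is to *benchmark* the candidates on the dataset at hand.

`ImputeBenchMS` does that. The benchmark's logic is:

1. extract the **complete submatrix** (features quantified in every
   sample), so that ground truth exists;
2. **mask** a fraction of its cells artificially, either uniformly (MCAR)
   or with intensity-dependent left-censoring (MNAR stress test);
3. **impute** with every candidate method;
4. **score** each result with four classic criteria (agreement between
   hidden truth and imputed values) and four proteomics-specific criteria
   (preservation of the co-expression structure biology imposes);
5. **normalize and rank**, per criterion family, and
6. optionally propagate the chosen imputation into **two-group
   differential expression** with a replicate-subsampling simulation.

## Data model

The central class is `ProteoSet`, a thin `SummarizedExperiment` with one
`"intensity"` assay, feature annotation (`peptide_sequence`, `charge`,
`protein_id`) in `rowData()` and the sample design in `colData()`. All
computation is on the **log2 scale**: intensities are approximately
log-normal, and constants such as "the global minimum" are only
meaningful once the scale is fixed. Raw-scale input is log2-transformed
on ingest, and raw zeros are treated as missing -- a zero in label-free
quantification is a non-detection, not an abundance of zero.

Protein complexes and interaction-map clusters come in as `GroupCatalog`
objects read from plain two-column TSVs, so any catalog (CORUM-style
complexes, hu.MAP-style clusters, or a user's own grouping) can be used;
the package deliberately ships no third-party database.

## The criteria

With `y_o` the hidden original values and `y_i` the imputed values at the
masked cells:

* **NRMSE** = sqrt(mean((y_o - y_i)^2) / var(y_o)), lower is better; the
  variance uses the n-1 denominator (sample variance), stated explicitly
  because the toy examples in the tests are asserted exactly.
* **SOR**: for each *variable* (feature) with masked cells, methods are
  ranked by their error on that variable; SOR is the rank total. The
  per-variable NRMSE denominator is the same for every method, so ranking
  by per-variable mean squared error is rank-identical and is what is
  computed -- this also covers variables with a single masked cell, where
  a variance-normalized error is undefined.
* **ACC_OI**: Pearson correlation of y_o against y_i. Constant imputers
  (zero, minimum, ...) have no imputed-value spread, so the correlation is
  undefined; the score is reported *missing with a reason* rather than
  silently dropped, and missing scores rank worst.
* **PSS**: both matrices are projected onto their first two principal
  components (samples as points); the imputed configuration is optimally
  translated, rotated/reflected and scaled onto the original
  (`vegan::procrustes`), and the criterion is the residual sum of
  squares. Two components are the default because sample-space QC plots
  in this field are two-dimensional; the count is configurable. Full
  similarity Procrustes (with scaling) is used, and PCA axis sign
  indeterminacy is absorbed by the rotation.

The proteomic criteria all have the same shape: average, over groups, of
the mean pairwise Pearson correlation between member profiles across
samples. The four levels are charge states within a peptide
(`accCharge`), peptides within a protein (`accPepProt`), proteins within
a complex (`accComplex`) and proteins within a PPI cluster (`accPpi`).
Only groups with at least two matched members count, and a pair is
skipped when either profile has zero variance. One genuinely open choice:
the group-level formulas can be read as dividing the pair-sum by the
member count m rather than by the number of unordered pairs m(m-1)/2.
Only the pair-count divisor yields a bounded average correlation, so it
is the default; `divisor = "m"` gives the literal alternative.

For complex/cluster criteria on peptide-level matrices, features are
first aggregated to protein profiles by the mean of the top-3 most
abundant members (the usual Top3 protein summarization); `aggregate =
"mean"` uses all members. Pre-imputation reference values use
pairwise-complete samples; post-imputation values use all samples.

## Masking

Masks contain exactly `round(p * cells)` coordinates (half away from
zero) and are stored in row-major order so evaluation vectors are
bit-reproducible. MCAR masks are uniform draws; the left-censored
mechanism draws cells with probability proportional to
`plogis(strength * (tau - x))` with `tau` the matrix's 10th percentile
and `strength = 5` per log2 unit -- the same censoring model the
synthetic generator uses, so "MNAR-only masking" means one thing
throughout the package. Sampling uses random priority keys
(Efraimidis-Spirakis), and a candidate cell is skipped when masking it
would empty a feature row or a sample column, because several imputers
are undefined there; when that constraint never binds (the common case)
the draw is exactly uniform/weighted sampling without replacement. The
robustness sweep covers 5% to 70% in steps of 5% -- 14 independent
masks.

## The method suite

Registry keys, by family: single-value (`zero`, `minimum`, `colmedian`,
`rowmedian`, plus the left-censored `mindet`, `minprob`, `pi`, `qrilc`),
global-structure (`svd`, `mle`, `impseq`, `impseqrob`), local-similarity
(`knn`, `seqknn`, `lls`, `grr`) -- that is the fast tier -- and the slow
chained-equations tier (`mice_norm`, `mice_cart`, `rf`, `irm`). `bpca`,
`trknn` and `gms` are documented plugin slots for `registerImputer()`.
Every method honours one contract: observed cells are preserved
bit-for-bit, the result is complete, and identical (input, parameters,
seed) gives identical output.

Parameter defaults follow common practice where the method families have
canonical reference implementations: KNN and LLS use k = 10 neighbours,
SVD rank 5, MinDet/MinProb the 1% quantile, the Perseus-style `pi` draw
a 1.8 SD downshift with 0.3 SD width. Choices that were genuinely open:

* **QRILC approximation.** The left-censored tail model is fitted by
  quantile-quantile regression of the upper 75% of observed quantiles on
  normal quantiles; imputed values are drawn from the fitted normal
  truncated above at the sample minimum. Samples with fewer than five
  observed values fall back to deterministic low-quantile replacement
  with a warning.
* **LLS shrinkage.** Local least squares on few observed samples
  extrapolates wildly (a regression with ~8 observations and 10
  neighbours is ill-posed), so the neighbour count is capped at
  n_obs - 1 and the coefficients carry a small relative ridge (1e-3 of
  the mean regressor energy). This leaves exact-recovery behaviour
  intact at `ridge = 0` and makes the method usable at realistic sample
  counts.
* **Impseq seeding.** The sequential conditional-mean imputer seeds its
  location/scatter from the complete features when at least
  n_samples + 1 of them exist; under heavy masking it seeds from
  pairwise-complete moments instead, with small covariance eigenvalues
  floored at 5% of the average eigenvalue -- those eigenvalues are
  estimation noise and would otherwise explode the conditional means.
* **Chained-equations predictor selection.** Each incomplete feature is
  regressed on its 10 most-correlated peers rather than literally all
  others: with far more features than samples the per-feature
  regressions (Bayesian linear, Huber, trees, forests) would be
  singular; correlation-based predictor pre-selection is standard
  chained-equations practice. `grr` (generalized-ridge flavour) is the
  ridge engine of the same machinery and is labelled a stand-in.
* **KNN conventions.** Distances are normalized Euclidean over jointly
  observed samples; zero-distance neighbours get uniform weights (1/0 is
  undefined); distance ties break by feature input order.

## Ranking

Raw scores are max-normalized so that the best method scores 1 on every
criterion: higher-is-better scores are divided by their maximum, and
lower-is-better scores (NRMSE, SOR, PSS) are mapped to min/value --
dividing those by their maximum would award 1 to the *worst* method. Raw
values are always retained alongside. Per criterion, methods are ranked
(average ties; a missing score ranks last -- a method that produces
undefined correlations should not benefit from them). Composite ranks
are the weighted mean of per-criterion ranks within a family (classic /
proteomic), ranked again; two composite tables are always produced, and
weights are user-configurable with zero meaning "drop the criterion".
`finalCheck()` flags criteria whose normalized-score range across
methods falls below 0.05 -- a flat criterion carries no selection signal
on that dataset. `targetedCheck()` shows, per feature and method, what
was filled in and whether it escapes the feature's observed range.

## Differential expression

Per feature, a two-tailed Student's t-test (pooled variance, because the
procedure is named after Student's test; Welch is a flag away),
Benjamini-Hochberg correction across features, and the conjunction call
rule BH-adjusted p < 0.05 and |log2 FC| > 0.585 (= log2 of a 1.5-fold
change). The fold change is first-group mean minus second-group mean,
first group meaning the first label in the design table. A feature with
zero variance in both groups and equal means gets p = 1 by convention.
`subsampleDE()` redraws k replicates per group without replacement
(e.g. "Random 5" / "Random 3" against a 10 + 10 gold standard), repeats,
and reports per-repeat significant counts plus per-feature medians of
the adjusted p-values and fold changes for volcano construction -- the
medians are taken independently, so a reported (p, FC) pair need not
co-occur in any single repeat. `goldStandardCompare()` reduces the
comparison to set overlap and a Jaccard index.

## The synthetic generator

`generateDataset()` emulates a mid-size two-condition DIA experiment:
protein base abundances Normal(22, 2) on log2; per-sample protein
signals add a complex latent factor and protein noise, scaled so that
peptides of one protein correlate at 0.8 and proteins of one complex at
0.7 by construction; peptides add an offset and Normal(0, 0.3) noise,
charge states an offset and half that noise; 200 proteins at 2-5
peptides and 1-3 charges (~1400 features), 10 replicates per group, 10%
differential proteins at 1 log2 unit. Complexes partition the proteins
(disjoint membership, as a latent-factor model requires), and PPI
clusters are complexes with up to two extra members -- interaction-map
clusters recover complexes imperfectly. The parameters were chosen once
so the original-matrix co-expression criteria land in the mid-range
(~0.5-0.9) where the criteria can actually discriminate methods.

What the generator does *not* emulate -- and what passing tests therefore
do not show about real data: retention-time drift, batch effects,
shared/razor peptides, interference, identification-level FDR, and
missingness produced by an actual instrument. `injectMissingness()`
overlays MCAR and left-censored MNAR cells with the logistic censoring
model described above.

## Numerical choices and degenerate inputs

Sample variance (n-1) throughout; masked-cell counts round half away
from zero; per-stage seeds derive from one global seed by a fixed affine
map so stages can be replayed in isolation; the EM imputer regularizes
its covariance by a 1e-6 ridge per M-step and reports
iterations/convergence; SVD imputation stops when the relative change of
the imputed cells drops below 1e-2 (configurable) and returns its best
iterate flagged unconverged otherwise; zero-variance features, samples
with no observations, groups below two members, and methods that fail
mid-batch all produce explicit errors, warnings or reasoned missing
scores rather than NaNs.

## Problem sizes used in the checks

The shipped verification runs use the generator at its default size
(~1400 features, 10 vs 10 samples) with 25 seeds for the
method-vs-mechanism orderings (structure-aware beats constant fills
under MCAR; left-censored beats column-median under MNAR), a 60-protein
fixture with 20 seeds for the classic-vs-proteomic ranking concordance,
and 20 repeats for the subsampling power ordering -- sizes at which the
expected orderings are decisive while a full run stays in the
minutes range on one CPU.

## Limitations

The benchmark scores imputations against *masked complete data*; features
that are never complete contribute no ground truth, and a complete
submatrix is biased toward abundant features. The MNAR stress test uses
one specific censoring model. Criteria agreement on synthetic data is a
consistency check, not evidence about any particular real dataset --
that is precisely why the tool exists: run it on your own matrix.
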