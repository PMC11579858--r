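---
title: "Methods: gene ranking, incremental feature selection and evaluation in scIFS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene ranking, incremental feature selection and evaluation in scIFS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scIFS)
```

## The problem and the model

Given a labelled cells × genes count matrix — typically a droplet
scRNA-seq reference in which each cell carries a subpopulation label
such as *B-cells* or *Cancer Epithelial* — `scIFS` searches for the
smallest gene subset that predicts the label well, and quantifies how
well. The search is a composition of three ideas:

1. **Filter ranking.** Each gene is scored for class-discriminative
   importance by a cheap filter statistic, independently of any
   classifier. Three filters with different inductive biases are
   provided; genes scoring ≤ 0 (or whose score is undefined) are
   excluded before ranking, so every ranking contains only genes with
   positive evidence under its own criterion.
2. **Incremental feature selection (IFS).** Nested prefixes of a
   ranking are evaluated by a classifier under stratified k-fold
   cross-validation. Because the curve typically saturates, the optimal
   subset is the smallest prefix achieving the maximum CV accuracy,
   and the walk stops early once a patience budget of non-improving
   sizes is spent.
3. **Model selection across combinations.** Sweeping all scorer ×
   classifier pairs (12 with the full roster) and choosing the pair
   with the highest optimal CV accuracy — ties resolved toward fewer
   genes — selects both the marker panel and the predictor.

## Gene-importance scores

### F-score

For two cell sets (positive/negative) and gene $i$ with class means
$\bar x_i^+,\ \bar x_i^-$, global mean $\bar x_i$, and within-class
sample variances $s_i^{+2},\ s_i^{-2}$:

$$F_i \;=\; \frac{(\bar x_i^+ - \bar x_i)^2 + (\bar x_i^- - \bar x_i)^2}
                 {s_i^{+2} + s_i^{-2}}.$$

The statistic is invariant to shifting and rescaling a gene, so raw
counts are usable directly. With $K>2$ classes each class is scored
one-vs-rest and the $K$ binary scores are averaged (the arithmetic mean
is the default; the per-class maximum is available via
`aggregate = "max"` for users who want genes that nail a single class).
Two numerical choices matter:

- A gene with zero within-class variance but nonzero separation would
  divide by zero; the denominator carries a guard of $10^{-12}$, so
  perfectly separating genes receive finite, very large scores and sort
  first rather than becoming `NaN`.
- A gene constant everywhere has a zero numerator and is defined as
  score 0, hence excluded.

### CV² above a fitted technical baseline

Per gene, the observed squared coefficient of variation is
$\mathrm{CV}^2 = s^2/\bar x^2$ (sample variance over squared mean,
computed in one sparse pass). Across genes the technical component of
CV² falls with the mean approximately as

$$\mathrm{CV}^2(\mu) \;=\; \frac{a_1}{\mu} + a_0,$$

which is fitted by a gamma-family, identity-link generalized linear
model of observed CV² on $1/\mu$ — the standard approach for this
regression in single-cell work, here through `stats::glm` with the
ordinary-least-squares line as starting values (falling back to that
line if the gamma iterations cannot complete on a degenerate input).
The importance score is $\log_2(\mathrm{CV}^2_{obs} /
\mathrm{CV}^2_{fit})$: a gene exactly on the technical baseline scores
0 and is excluded, which makes the global "≤ 0 excluded" rule coincide
with the biological reading (no excess variability, no interest).
Zero-mean genes are skipped with a warning; a matrix whose usable genes
share a single mean value cannot constrain the two parameters and is
rejected as degenerate.

### PCA loading importance

The matrix is standardized gene-wise and decomposed by PCA; gene $i$
scores $\sum_j |\ell_{ij}|\, v_j$ over the first $k$ components, where
$\ell_{ij}$ is the loading and $v_j$ the explained-variance ratio. By
default $k$ covers 90% of variance; an explicit `n_components`
overrides. Constant genes have no defined standardization and are
pinned to score 0 (excluded) rather than propagating a division by
zero. This scorer is label-free: it favours genes aligned with the
dominant axes of variation, which in well-separated data are the class
axes, but it can be distracted by strong label-independent structure —
that is precisely why it is one of three views rather than the only
one.

## Classifiers and grid search

Four families, one uniform surface (`classifier_spec()`,
`train_classifier()`, `predict_proba()`):

| family | implementation | default grid |
|---|---|---|
| knn | package-internal vote counting | k ∈ {1, 5, 15, 31} |
| svm | `e1071::svm`, RBF kernel, Platt probabilities | C ∈ {0.1, 1, 10}, γ = 1/(p·Var X) |
| rfc | `ranger`, probability forest | trees ∈ {100, 500}, depth ∈ {∞, 10} |
| xgboost | `xgboost`, multi:softprob | trees ∈ {100, 300}, depth ∈ {3, 6}, η ∈ {0.1, 0.3} |

The grids are package defaults, fully overridable per run; CV accuracy
is the selection criterion and ties go to the first grid point in
declaration order. kNN probability rows are neighbour vote fractions
(Euclidean distance, distance ties broken by training order), written
in-package because the classical `class::knn` interface exposes only
the winning-class probability while the module contract requires full
per-class rows. Hard predictions are defined as the argmax of
`predict_proba` for every family, so probabilities and labels can never
disagree; for the margin-based SVM the Platt-calibrated argmax is
asserted against the decision rule on clean separable toys in the test
suite. All stochastic components — fold shuffling, forest and boosting
randomness, Platt's internal cross-validation — derive from the single
spec seed, making retraining bit-reproducible.

Stratified folds are dealt per class round-robin after a seeded
shuffle, so fold class proportions deviate by at most one cell.

## IFS mechanics

The schedule of subset sizes defaults to 10 geometrically spaced sizes
from 10 to the ranking length: gene-importance curves are long-tailed,
so geometric spacing spends resolution where the curve moves. "No
further improvement" is made operational as patience-based stopping
(default 3 consecutive sizes not exceeding the running maximum). CV
folds are a function of the labels and the seed only, hence identical
across subset sizes — curves are comparable point to point, and an
equal-accuracy tie is resolved toward the smaller size, which is also
how the winning combination is chosen in the sweep (a model with equal
accuracy and 50× fewer genes is the better model). In a sweep, a shared
schedule is truncated to each ranking's length, since rankings differ
in length after exclusion.

One subtlety is worth stating: the minimal-subset rule interacts with
marker redundancy. If a class has ten good markers, a prefix containing
six of them may already saturate CV accuracy, and the plateau rule will
— correctly — stop there. Recovery of *all* planted markers is
therefore expected only when markers are individually moderate and
jointly necessary; on occasional draws the curve saturates early and
the selected panel covers a subset of the ground truth.

## Evaluation conventions

Multiclass metrics are one-vs-rest per class, macro-averaged
(unweighted): accuracy is trace over total of the confusion matrix;
macro F1 is the mean of per-class F1 values, **not** the harmonic mean
of macro precision and recall (the two differ; the convention is
pinned by a test where they disagree). Ratios of the form 0/0 (a class
never predicted, or absent from the truth) are reported as 0 with a
warning so no report contains `NaN`; micro averages are emitted
alongside for transparency. ROC curves sweep the threshold over tied
score groups jointly; the trapezoidal AUC then equals the
positive-outranks-negative probability with ties counting one half,
which the tests verify against exhaustive pair counting. The headline
AUC of a multiclass run is the macro one-vs-rest AUC.

## The synthetic generator

`generate_synthetic()` draws counts from a negative binomial with
gene-wise baseline means log-uniform over `baseline_mean_range`
(default 0.1–3 counts per cell, the regime of moderately expressed
genes in UMI data) and common dispersion (default size 5, i.e.
variance $\mu + \mu^2/5$). `n_informative` genes (default 50) are
assigned to classes round-robin — every class gets markers — and their
mean is multiplied by $2^{\text{effect\_log2fc}}$ (default 4×) in that
class. Optional extra zero-inflation (`dropout_extra`) masks entries
independently. The default class inventory, 773/1184/897/1020/1000
cells in five classes, mirrors a published five-subpopulation breast
tumour reference in shape.

What the generator emulates: sparse overdispersed counts, imbalanced
classes, a small planted marker set among thousands of null genes.
What it does not: gene–gene correlation beyond the class structure,
batch effects, library-size gradients, doublets, ambient RNA. Passing
tests on this harness therefore demonstrate that the machinery ranks,
selects and evaluates correctly — not that any particular biological
dataset will yield a 50-gene panel.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run the full study at a
deliberately compact scale chosen to exercise every stage with clear
margins: 5 classes × 100 cells × 2,000 genes with 50 planted markers
for the end-to-end recovery runs (three seeds), 500 genes × 500 cells
for CV²-parameter recovery (the NB size-10 construction makes the true
curve $\mathrm{CV}^2 = 1/\mu + 0.1$ exactly), and 100 cells × 120
genes for the 12-combination sweep. The compact xgboost grid used
there (150 trees, depth ∈ {3, 6}) is a configuration choice, as grids
always are in this package.

## QC, splitting and preprocessing

QC keeps cells with strictly more than 200 detected genes, strictly
more than 250 UMIs and a mitochondrial fraction strictly below 20%
(all configurable); mitochondrial genes are recognised by a
case-insensitive id prefix (`MT-`), which is a convention, not a
biological fact — datasets with other nomenclatures must set it.
Splitting is stratified with per-class test counts
`round(class_size × test_fraction)` under a mandatory seed.
Classification runs on raw counts by default; `normalize_cpm()`
(counts-per-million, log1p) is available behind a flag because the
F-score is scale-invariant per gene but the distance-based kNN and SVM
are not, and users should make that choice deliberately.

## Known limitations

- IFS searches prefixes only; it will not find a small non-contiguous
  subset that beats every prefix (wrapper search is out of scope).
- CV accuracy of the selected subset is an optimistically biased
  estimate of generalization (selection and estimation share the same
  folds); the held-out split exists precisely to report an unbiased
  number, and no nested cross-validation is attempted.
- The PCA scorer standardizes genes, which equalizes scale; for
  near-constant genes this amplifies noise, mitigated only by the
  excluded-at-zero rule.
- `apply_qc` is intentionally simple threshold filtering; ambient-RNA
  and empty-droplet modelling belong upstream.
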