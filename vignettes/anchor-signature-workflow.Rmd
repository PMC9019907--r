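---
title: "Anchor-gene prognostic signatures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-gene prognostic signatures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatsig)
```

## The scientific problem

In head and neck squamous cell carcinoma (HNSCC), the tumor-suppressor
*FAT1* is among the most frequently mutated genes, yet neither its mutation
status nor its mRNA level alone separates patients by outcome cleanly. A
productive alternative is to build a *signature* of genes that are jointly
coupled to the anchor gene on both axes — differentially expressed between
anchor-mutated and wild-type tumors *and* correlated with the anchor's own
mRNA level — and to stratify patients on that signature rather than on the
anchor itself. `fatsig` implements this workflow end to end for any anchor
gene, together with the machinery needed to carry a risk stratification
from a training cohort into independent cohorts profiled on different
platforms, and a synthetic multi-cohort generator so that every stage can
be exercised and scored against known truth without any external data.

## Signature derivation

For each gene the package computes, on a log2 expression matrix:

* the log2 fold change `log2fc = mean(mutated) - mean(wild-type)` and the
  linear fold change `FC = 2^log2fc`;
* the pooled-variance two-sample Student *t* statistic and its two-sided
  p-value on `n1 + n0 - 2` degrees of freedom (Welch's correction is
  available behind a flag, but Student's form is the default since it is
  the classical choice for this filter);
* the Pearson correlation *r* of the gene with the anchor gene across all
  samples, with the exact p-value from
  `t = r * sqrt((n - 2) / (1 - r^2))`.

A gene joins the signature when it passes all four criteria at once:
`FC >= 1.5`, t-test `p < 0.05`, `|r| > 0.2`, and correlation `p < 0.05`.
Two reading choices deserve comment:

* **Fold change is direction-agnostic by default**: the criterion is
  `max(FC, 1/FC) >= 1.5`. Signatures of this kind typically contain both
  up- and down-regulated members, and a one-sided `FC >= 1.5` rule would
  silently discard the down-regulated half. A `fc_directional` flag
  restores the one-sided reading.
* **No multiple-testing correction is applied by default** — the filter
  operates on raw p-values, which is how this class of four-criterion
  screens is usually specified. An optional Benjamini–Hochberg mode
  (`fdr = TRUE`) is provided for users who prefer FDR control; with ~20k
  genes the raw-p screen relies on the conjunction of four criteria, not
  on any single p-value, for its specificity (the null-calibration tests
  show the conjunction's false-positive fraction is far below any single
  criterion's level).

Genes with zero within-group variance cannot carry a t statistic; they are
flagged, excluded from selection, and counted in a warning rather than
passed through as infinite fold changes.

## Patient stratification

Training-cohort patients are clustered on the signature-gene submatrix by
agglomerative **complete linkage** under the **centered correlation
distance** `d = 1 - r` between sample profiles (the "correlation
(centered)" similarity of the classic Cluster 3.0 program, as a distance).
`d = 1 - r` rather than `1 - |r|` is deliberate: anticorrelated patients
are maximally distant. Genes are z-scored (row-normalized) before
clustering by default, the convention under which signature heatmaps are
drawn; a raw-scale flag exists.

The linkage is implemented in the package rather than delegated to
`stats::hclust` for one reason: a deterministic, input-order-invariant
tie-break. When several cluster pairs attain the minimal distance, the
pair whose smallest member IDs sort lexicographically first is merged.
`hclust` serves as an independent oracle in the test suite — merge heights
agree to 1e-12 on random matrices — but its tie behavior depends on input
order, which would make run manifests irreproducible under column
permutations.

Cutting the final merge yields two clusters. The high-risk (HR) label goes
to the cluster with the higher anchor-mutation rate; on an exact tie, to
the cluster with the higher mean anchor expression; on a further tie, to
the larger cluster. This hierarchy turns the reported HR-subgroup
characteristics (higher mutation rate, higher anchor expression) into a
total, deterministic rule; the rule that fired is recorded in the labels'
`labeling_basis` attribute.

## Cross-cohort transfer: the Bayesian compound covariate predictor

Expression from different platforms (RNA-seq, two microarray families) is
not comparable on the raw scale, so every cohort is first standardized
gene-wise within itself: `z = (x - mean) / sd`. Standardization is
idempotent and erases per-gene location/scale platform effects by
construction, which is exactly the class of distortion the synthetic
generator plants.

The classifier is the **Bayesian compound covariate predictor (BCCP)** in
the tradition of the BRB-ArrayTools class-prediction engine. On the
standardized training matrix:

* each signature gene *j* gets weight `t_j`, its pooled-variance
  two-sample t statistic between the HR and LR training classes;
* each sample *i* is reduced to the scalar compound covariate
  `c_i = sum_j t_j x_ij`;
* `c` is modeled as Gaussian within each class with means `mu_LR`,
  `mu_HR` and a **pooled** (equal-variance) SD `sigma`;
* a new sample's posterior probability of the HR class is
  `P(HR | c) = pi_HR phi(c; mu_HR, sigma) / [pi_HR phi(c; mu_HR, sigma) +
  pi_LR phi(c; mu_LR, sigma)]`, computed in log space; with equal
  variances this reduces to the logistic form
  `1 / (1 + exp(-(mu_HR - mu_LR)(c - (mu_HR + mu_LR)/2) / sigma^2))`,
  which the tests verify to 1e-10.

Default priors are 0.5/0.5 (the BRB default; an `"empirical"` option uses
training class proportions) and the decision threshold is a posterior of
0.5, so every patient receives a class — no "no-call" band — because the
workflow requires a total stratification of each validation cohort.

Classifier robustness is estimated by **leave-one-out cross-validation**:
weights and Gaussian parameters are refit on each `n - 1` subset and the
held-out sample is predicted. The signature gene set is held fixed across
folds — the signature is derived once, before classification, and the
LOOCV estimates the classifier's error given that signature, not the
selection's. Folds whose remainder loses a class below two members are
skipped with an adjusted denominator.

## Survival machinery

Overall survival (diagnosis to death) and recurrence-free survival
(diagnosis to recurrence) are analyzed in months. All "five-year"
comparisons first apply **administrative censoring at 60 months** (times
beyond the horizon become censored observations at the horizon); a
no-truncate option preserves full follow-up. Kaplan–Meier curves,
log-rank tests, and Cox proportional-hazards models (univariate and
multivariate) are delegated to the `survival` package, with **Breslow**
tie handling as the default (Efron behind a flag) and complete-case
covariate handling, mirroring how "Unknown" clinical categories are
excluded per analysis. The multivariate covariate set is risk label plus
age group, sex, smoking, T and N classification, with further covariates
at the user's discretion per cohort availability.

The treatment-interaction test fits `Surv ~ risk * treatment` and reports
the Wald p-value of the product term, after verifying all four cells of
the 2x2 table are populated. ROC/AUC analysis (with the DeLong CI and the
Youden-index threshold, ties broken toward higher sensitivity) is
delegated to `pROC`; the test suite pins the AUC to exhaustive
concordant-pair counting.

## The synthetic multi-cohort generator

The generator emulates the statistical structure the pipeline assumes:

* a latent two-class risk structure (`frac_hr`, default 0.6 — close to the
  roughly 65/35 HR/LR split reported for this kind of training cohort);
* anchor mutation with class-specific rates (defaults 0.26 / 0.13, the
  reported subgroup mutation rates rounded);
* a planted signature of 25 genes with alternating direction signs, each
  shifted `delta_log2 = 1.5` log2 units by mutation (a structural,
  within-subgroup effect) and `group_shift_log2 = 3` log2 units between
  the latent subgroups;
* a target marginal Pearson correlation `rho = 0.5` between each
  signature gene (direction-signed) and the anchor;
* exponential proportional-hazards survival (baseline 0.015
  events/month, subgroup hazard ratio 2, radiotherapy hazard ratio 0.7,
  optional treated-by-HR interaction), independent exponential censoring
  (0.005/month) capped administratively at 120 months;
* per-gene platform shifts for non-training cohorts: additive offsets
  `N(0, 0.8)` and multiplicative scales `exp(N(0, 0.2))`.

### How the correlation target is met

A gene's correlation with the anchor has two possible sources: a shared
latent factor, and the subgroup/mutation structure that moves both the
gene and the anchor. A pure latent-factor design is appealing analytically
but has a cost: any factor strong enough to carry `r = 0.5` at unit noise
adds within-subgroup variance to every signature gene, which blurs the
patient clusters and makes faithful subgroup recovery (adjusted Rand
index around 0.8 at the stated defaults) unattainable under
correlation-distance complete linkage. The generator therefore lets the
**structure itself carry the correlation**: all first and second moments
of the planted model are available in closed form (subgroup membership is
Bernoulli, mutation is Bernoulli within subgroup, noise is Gaussian), so
the generator solves analytically for the anchor's subgroup shift such
that the marginal gene–anchor correlation equals `rho` exactly in
expectation. Only when the requested `rho` *exceeds* what the structure
can supply is a residual shared latent factor added, with its loading
solved by the same moment calculation. Targets below what the structure
already induces are rejected with an explanatory error rather than
silently missed. A Monte-Carlo test (50 replicates at n = 300) confirms
the empirical correlation lands within ±0.1 of the target and the
subgroup-stratified mutation shift within ±0.15 of `delta_log2`.

### The mutation/expression sign tension

Published data for this anchor show an apparent paradox: mutated tumors
express *less* anchor mRNA marginally, while the high-risk subgroup has
both the *higher* mutation rate and the *higher* anchor expression. The
generator reproduces exactly this tension: the mutation effect on the
anchor is a signed knob (`mut_anchor_shift`, default -0.5 log2) while the
subgroup shift on the anchor is positive, so the marginal mutation
contrast and the subgroup contrast pull in opposite directions, just as
reported. Users who want the opposite sign set the knob positive.

### What the generator does not emulate

Expression is Gaussian on the log2 scale — there is no count-level
(negative-binomial) noise, no mean–variance trend, no probe-level
artifacts, and no gene–gene correlation beyond the planted structure.
Clinical covariates other than radiotherapy are independent of survival
by design (so null Cox coverage is testable). HPV status is an
independent binary tag, not a biological confounder. Consequently,
passing recovery tests demonstrates that the pipeline's statistics do
what they claim on data satisfying their assumptions; they do not certify
performance on real RNA-seq/microarray cohorts with probe collapse
ambiguity, batch structure, or informative censoring.

## Numerical and design choices

* Exact-equality checks back the risk-labeling tie hierarchy; ties in
  floating-point mutation rates are exact ties of rational counts, so the
  hierarchy is well defined.
* Linkage ties are detected with a relative 1e-12 tolerance and resolved
  by the lexicographic rule above.
* TSV is the canonical table dialect (tab-separated, UTF-8, `.` decimal),
  with expression values written at 17 significant digits so write/read
  round trips are bit-faithful; signature and model files are JSON with a
  schema version that is checked on read.
* Readers reject structural problems (duplicate IDs, non-numeric cells,
  negative times, non-binary flags) rather than coercing; unrecognized
  clinical category tokens become missing values and are counted in a
  single warning.
* Degenerate inputs (constant genes, single-class labelings, empty
  interaction cells, single-class ROC calls) raise errors or logged
  exclusions; nothing is silently imputed.
* Run manifests record MD5 digests of every artifact; the discovery and
  validation stages are deterministic, so reruns on identical inputs
  reproduce identical digests.

## Problem sizes used by the test suite

The suite works at the study's own scale where that is cheap and at
reduced scale where exhaustive oracles are the point: selection nulls use
2000 genes x 300 samples (20 replicates), recovery runs use the generator
defaults (300 samples/cohort, 1000 genes, 25 planted genes, 25
replicates), log-rank and interaction null calibrations use 500
replicates of compact cohorts, Cox recovery pools five cohorts of 300
(100 replicates), and the brute-force oracles run at n <= 20 (permutation
t), n <= 7 (linkage enumeration), and n = 6 (LOOCV fold loop), where
exhaustive computation is exact.

## Known limitations

* Probe-to-gene collapse for array platforms is upstream of this package;
  matrices are assumed to carry one row per gene.
* The Cox layer offers no Firth-style fallback for complete separation;
  such fits error with a suggestion rather than returning inflated
  estimates.
* k is fixed at 2 for patient clustering; consensus clustering and k > 2
  are out of scope.
* The LOOCV default (fixed gene set) estimates classification error
  conditional on the signature, matching how such classifiers are usually
  reported; `loocv_error_full()` reselects the signature inside every fold
  for an honest whole-pipeline error estimate.
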