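# fatsig

Anchor-gene prognostic signature derivation and Bayesian compound
covariate risk classification for tumor expression cohorts.

## What this solves

In cancers such as head and neck squamous cell carcinoma, a frequently
mutated driver ("anchor") gene — *FAT1* being the motivating case — often
fails to stratify patients by outcome through its mutation status or mRNA
level alone. This package implements the alternative: derive a signature
of genes jointly coupled to the anchor on both the mutation and the
expression axis, cluster training-cohort patients on that signature into
low-risk (LR) and high-risk (HR) subgroups, carry the stratification into
independent cohorts profiled on other platforms, and quantify the
prognostic separation with standard survival machinery. A synthetic
multi-cohort generator with planted truth makes the whole workflow
testable offline and lets every stage be scored against known answers.

## The method

**Signature derivation.** On a log2 expression matrix, a gene joins the
signature when it passes all four criteria between anchor-mutated and
wild-type samples and against the anchor's expression:

1. fold change `FC = 2^(mean_mut − mean_wt) ≥ 1.5` (direction-agnostic:
   `max(FC, 1/FC)` is tested);
2. pooled-variance Student *t*-test `p < 0.05`;
3. Pearson correlation with the anchor `|r| > 0.2`;
4. correlation `p < 0.05` (from `t = r√((n−2)/(1−r²))`).

**Stratification.** Patients are clustered on the signature genes by
complete-linkage agglomeration under the centered correlation distance
`d = 1 − r`, with a deterministic lexicographic tie-break; the two
top-level clusters are labeled HR/LR by mutation rate, then anchor
expression, then size.

**Transfer.** After within-cohort z-score standardization, the Bayesian
compound covariate predictor (BCCP) reduces each sample to
`c_i = Σ_j t_j x_ij` (t-statistic weights), models `c` as Gaussian per
class with pooled variance, and assigns `P(HR | c)` by Bayes' rule;
robustness is estimated by leave-one-out cross-validation.

**Survival.** Five-year (60-month administrative censoring) Kaplan–Meier
curves, log-rank tests, univariate/multivariate Cox models (Breslow
ties), a risk-by-treatment interaction test, and ROC/Youden analysis.

See `vignettes/anchor-signature-workflow.Rmd` for the full methods
account, including how the generator calibrates the planted gene–anchor
correlation from closed-form moments.

## Worked example

```r
library(fatsig)

cfg <- sim_config(seed = 7)            # defaults: 300 samples/cohort,
cohorts <- simulate_multi_cohort(cfg)  # 1000 genes, 25 planted, 2 cohorts
train <- cohorts[[1]]

sig <- select_signature(train$expression, train$mutation, "FAT1")
sig
#> Signature of 25 genes coupled to anchor FAT1
#> thresholds: FC >= 1.5, t p < 0.05, |r| > 0.2, r p < 0.05

dend <- cluster_samples(train$expression[sig$genes$gene_id, ])
labels <- assign_risk_labels(cut_two(dend), train$mutation,
                             train$expression, "FAT1")
survival_report(train$clinical, labels, endpoint = "os", horizon = 60)
#> $logrank$p
#> [1] 1.060224e-07
#> $five_year
#>        HR        LR
#> 0.1563419 0.4593561

model <- fit_bccp(standardize(train$expression)$expression, labels, sig)
pred <- predict_bccp(model, standardize(cohorts[[2]]$expression)$expression)
table(pred$risk,
      cohorts[[2]]$truth_labels$group)   # balanced accuracy 0.988
```

The 25 selected genes are exactly the planted ones (sensitivity 1, false
discovery 0 at these defaults); the clustered HR subgroup shows the worse
five-year overall survival (15.6% vs 45.9%, log-rank p ≈ 1e-07); and the
classifier transfers the stratification across the platform-shifted
second cohort at 0.99 balanced accuracy.

The `analysis/` directory holds the same workflow as numbered narrative
drivers (`01_simulate.R` … `05_survival.R`) writing their tables under
`results/`.

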