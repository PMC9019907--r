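#!/usr/bin/env Rscript
# Train the Bayesian compound covariate predictor on the standardized
# training cohort (t-statistic gene weights, equal-variance Gaussian class
# model, 0.5/0.5 priors), estimate its leave-one-out misclassification,
# and transfer the LR/HR labels to the four platform-shifted validation
# cohorts after within-cohort z-score standardization.

suppressPackageStartupMessages(library(fatsig))

sig <- read_signature("results/signature.json")
labels <- read.delim("results/labels_training.tsv")

tr_expr <- read_expression("results/cohorts/training/expression.tsv")
std_tr <- standardize(tr_expr)$expression
model <- fit_bccp(std_tr, labels, sig)
write_bccp(model, "results/bccp_model.json")
cv <- loocv_error(std_tr, labels, sig)
cat(sprintf("LOOCV misclassification on training: %.4f (%d folds)\n",
            as.numeric(cv), attr(cv, "n_folds")))

for (nm in paste0("validation", 1:4)) {
  dir <- file.path("results/cohorts", nm)
  expr <- read_expression(file.path(dir, "expression.tsv"))
  truth <- read.delim(file.path(dir, "truth_labels.tsv"))
  pred <- predict_bccp(model, standardize(expr)$expression)
  write_table_tsv(pred, file.path("results", paste0("labels_", nm, ".tsv")))
  tg <- truth$group[match(pred$sample_id, truth$sample_id)]
  bacc <- mean(c(mean(pred$risk[tg == "HR"] == "HR"),
                 mean(pred$risk[tg == "LR"] == "LR")))
  cat(sprintf("  %-12s predicted HR %5.1f%%, balanced accuracy %.3f\n",
              nm, 100 * mean(pred$risk == "HR"), bacc))
}
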