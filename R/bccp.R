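#' Within-cohort z-score standardization
#'
#' Standardizes each gene to mean 0, SD 1 within one cohort — the step that
#' lets a classifier trained on one expression platform transfer to
#' another. Constant genes are dropped with a warning.
#'
#' @param expr expression matrix, genes x samples, >= 2 samples.
#' @return list with `expression` (standardized matrix) and `params`, a
#'   data.frame of the per-gene means and SDs used.
#' @export
standardize <- function(expr) {
  if (ncol(expr) < 2L) stop("standardization needs >= 2 samples")
  mu <- rowMeans(expr)
  sdv <- apply(expr, 1L, stats::sd)
  drop <- sdv == 0 | !is.finite(sdv)
  if (any(drop)) {
    warning("dropped ", sum(drop), " constant gene(s) during standardization")
    expr <- expr[!drop, , drop = FALSE]
    mu <- mu[!drop]
    sdv <- sdv[!drop]
  }
  list(expression = (expr - mu) / sdv,
       params = data.frame(gene_id = rownames(expr), mean = mu, sd = sdv,
                           stringsAsFactors = FALSE, row.names = NULL))
}

.pooled_t_weights <- function(x_hr, x_lr) {
  n1 <- ncol(x_hr)
  n0 <- ncol(x_lr)
  m1 <- rowMeans(x_hr)
  m0 <- rowMeans(x_lr)
  v1 <- rowSums((x_hr - m1)^2) / (n1 - 1L)
  v0 <- rowSums((x_lr - m0)^2) / (n0 - 1L)
  sp2 <- ((n1 - 1L) * v1 + (n0 - 1L) * v0) / (n1 + n0 - 2L)
  (m1 - m0) / sqrt(sp2 * (1 / n1 + 1 / n0))
}

.bccp_gaussian <- function(c_hr, c_lr) {
  n1 <- length(c_hr)
  n0 <- length(c_lr)
  mu_hr <- mean(c_hr)
  mu_lr <- mean(c_lr)
  pooled_var <- ((n1 - 1L) * stats::var(c_hr) +
                   (n0 - 1L) * stats::var(c_lr)) / (n1 + n0 - 2L)
  list(mu_hr = mu_hr, mu_lr = mu_lr, sd = sqrt(pooled_var))
}

#' Fit the Bayesian compound covariate predictor
#'
#' Each signature gene gets a pooled-variance two-sample t statistic (HR vs
#' LR on the standardized training matrix) as its weight; the compound
#' covariate of a sample is the weighted sum `c_i = sum_j t_j x_ij`. The
#' class-conditional distribution of `c` is modeled as Gaussian with class
#' means and a pooled (equal-variance) SD, and Bayes' rule with the given
#' priors converts a new sample's `c` into a posterior probability of the
#' high-risk class.
#'
#' @param expr_std standardized training matrix (genes x samples).
#' @param labels risk-label data.frame (`sample_id`, `risk` in LR/HR).
#' @param signature `fatsig_signature` (or character vector of gene IDs).
#' @param priors `c(lr, hr)` prior class probabilities summing to 1, or
#'   `"empirical"` for the training class proportions.
#' @param decision_threshold posterior cutoff for calling HR.
#' @return `fatsig_bccp` model: gene IDs, weights, class means, pooled SD,
#'   priors, threshold, and any signature genes missing from the matrix.
#' @export
fit_bccp <- function(expr_std, labels, signature, priors = c(0.5, 0.5),
                     decision_threshold = 0.5) {
  gene_ids <- if (inherits(signature, "fatsig_signature")) {
    signature$genes$gene_id
  } else {
    as.character(signature)
  }
  if (!length(gene_ids)) stop("empty signature")
  missing_genes <- setdiff(gene_ids, rownames(expr_std))
  if (length(missing_genes) == length(gene_ids)) {
    stop("no signature genes present in the training matrix")
  }
  if (length(missing_genes)) {
    warning(length(missing_genes),
            " signature gene(s) absent from training matrix, dropped")
  }
  gene_ids <- setdiff(gene_ids, missing_genes)
  risk <- labels$risk[match(colnames(expr_std), labels$sample_id)]
  if (anyNA(risk)) stop("risk labels missing for some training samples")
  n_hr <- sum(risk == "HR")
  n_lr <- sum(risk == "LR")
  if (n_hr < 2L || n_lr < 2L) {
    stop("both classes need >= 2 training samples (HR: ", n_hr,
         ", LR: ", n_lr, ")")
  }
  x <- expr_std[gene_ids, , drop = FALSE]
  w <- .pooled_t_weights(x[, risk == "HR", drop = FALSE],
                         x[, risk == "LR", drop = FALSE])
  if (any(!is.finite(w))) {
    stop("non-finite t-statistic weight; check for constant genes")
  }
  cc <- as.vector(crossprod(x, w))
  gauss <- .bccp_gaussian(cc[risk == "HR"], cc[risk == "LR"])
  if (gauss$sd <= 0) stop("degenerate compound covariate (zero spread)")
  if (identical(priors, "empirical")) {
    priors <- c(n_lr, n_hr) / (n_lr + n_hr)
  }
  stopifnot(length(priors) == 2L, all(priors >= 0),
            abs(sum(priors) - 1) < 1e-8)
  structure(list(gene_ids = gene_ids, weights = stats::setNames(w, gene_ids),
                 mu_lr = gauss$mu_lr, mu_hr = gauss$mu_hr,
                 pooled_sd = gauss$sd,
                 priors = stats::setNames(priors, c("LR", "HR")),
                 decision_threshold = decision_threshold,
                 missing_genes = missing_genes),
            class = "fatsig_bccp")
}

#' Predict risk classes with a fitted BCCP model
#'
#' Computes the compound covariate from the model weights restricted to
#' genes shared with the (already standardized) target matrix and applies
#' Bayes' rule under the equal-variance Gaussian class model. Posteriors
#' for LR and HR sum to 1 exactly.
#'
#' @param model `fatsig_bccp` from [fit_bccp()].
#' @param expr_std standardized target matrix (genes x samples), z-scored
#'   within its own cohort.
#' @return data.frame with `sample_id`, `score` (compound covariate),
#'   `posterior_hr`, `risk`, `provenance = "predicted"`.
#' @export
predict_bccp <- function(model, expr_std) {
  stopifnot(inherits(model, "fatsig_bccp"))
  shared <- intersect(model$gene_ids, rownames(expr_std))
  if (!length(shared)) stop("no model genes present in target matrix")
  if (length(shared) < 0.5 * length(model$gene_ids)) {
    warning("fewer than 50% of model genes present in target matrix (",
            length(shared), "/", length(model$gene_ids), ")")
  }
  cc <- as.vector(crossprod(expr_std[shared, , drop = FALSE],
                            model$weights[shared]))
  # log-space Bayes for numerical safety
  log_hr <- log(model$priors["HR"]) +
    stats::dnorm(cc, model$mu_hr, model$pooled_sd, log = TRUE)
  log_lr <- log(model$priors["LR"]) +
    stats::dnorm(cc, model$mu_lr, model$pooled_sd, log = TRUE)
  posterior_hr <- 1 / (1 + exp(log_lr - log_hr))
  data.frame(sample_id = colnames(expr_std), score = cc,
             posterior_hr = posterior_hr,
             risk = ifelse(posterior_hr > model$decision_threshold,
                           "HR", "LR"),
             provenance = "predicted",
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Leave-one-out cross-validated misclassification rate
#'
#' For each training sample the weights and Gaussian parameters are refit
#' on the remaining samples (gene set held fixed) and the held-out sample
#' is predicted; the rate is errors over evaluated folds. Folds whose
#' remainder loses a class below two members are skipped with a warning
#' and removed from the denominator.
#'
#' @inheritParams fit_bccp
#' @return misclassification rate in [0, 1], with attributes `n_folds`
#'   (evaluated) and `n_skipped`.
#' @export
loocv_error <- function(expr_std, labels, signature, priors = c(0.5, 0.5),
                        decision_threshold = 0.5) {
  n <- ncol(expr_std)
  if (n < 4L) stop("LOOCV needs >= 4 samples")
  risk <- labels$risk[match(colnames(expr_std), labels$sample_id)]
  errors <- 0L
  evaluated <- 0L
  skipped <- 0L
  for (i in seq_len(n)) {
    rest <- risk[-i]
    if (sum(rest == "HR") < 2L || sum(rest == "LR") < 2L) {
      skipped <- skipped + 1L
      next
    }
    fit <- fit_bccp(expr_std[, -i, drop = FALSE],
                    data.frame(sample_id = colnames(expr_std)[-i],
                               risk = rest, stringsAsFactors = FALSE),
                    signature, priors = priors,
                    decision_threshold = decision_threshold)
    pred <- predict_bccp(fit, expr_std[, i, drop = FALSE])
    evaluated <- evaluated + 1L
    if (pred$risk != risk[i]) errors <- errors + 1L
  }
  if (skipped > 0L) {
    warning(skipped, " LOOCV fold(s) skipped (single-class remainder)")
  }
  if (evaluated == 0L) stop("no evaluable LOOCV folds")
  structure(errors / evaluated, n_folds = evaluated, n_skipped = skipped)
}

#' Leave-one-out error with per-fold signature reselection
#'
#' The honest-error variant of [loocv_error()]: each fold re-runs the
#' four-criterion signature selection on the remaining samples (on the raw
#' log2 matrix, since fold change is not meaningful after z-scoring),
#' re-standardizes within the fold, refits the BCCP and predicts the
#' held-out sample with the fold's standardization parameters. This
#' estimates the error of the whole derive-train pipeline rather than of
#' the classifier conditional on a fixed signature.
#'
#' @param expr raw log2 expression matrix (genes x samples).
#' @param labels risk-label data.frame (`sample_id`, `risk`).
#' @param mutation mutation data.frame for the reselection step.
#' @param anchor anchor gene ID.
#' @param thresholds selection thresholds, see [default_thresholds()].
#' @param priors,decision_threshold as in [fit_bccp()].
#' @return misclassification rate with attributes `n_folds`, `n_skipped`
#'   (folds without >= 2 reselected genes or a two-class remainder).
#' @export
loocv_error_full <- function(expr, labels, mutation, anchor,
                             thresholds = default_thresholds(),
                             priors = c(0.5, 0.5),
                             decision_threshold = 0.5) {
  n <- ncol(expr)
  if (n < 4L) stop("LOOCV needs >= 4 samples")
  risk <- labels$risk[match(colnames(expr), labels$sample_id)]
  errors <- 0L
  evaluated <- 0L
  skipped <- 0L
  for (i in seq_len(n)) {
    rest <- risk[-i]
    if (sum(rest == "HR") < 2L || sum(rest == "LR") < 2L) {
      skipped <- skipped + 1L
      next
    }
    tr <- expr[, -i, drop = FALSE]
    mut_i <- mutation[mutation$sample_id %in% colnames(tr), , drop = FALSE]
    sig_i <- suppressWarnings(
      select_signature(tr, mut_i, anchor, thresholds = thresholds))
    if (nrow(sig_i$genes) < 2L) {
      skipped <- skipped + 1L
      next
    }
    std_i <- suppressWarnings(standardize(tr))
    fit <- fit_bccp(std_i$expression,
                    data.frame(sample_id = colnames(tr), risk = rest,
                               stringsAsFactors = FALSE),
                    sig_i, priors = priors,
                    decision_threshold = decision_threshold)
    # standardize the held-out sample with the fold's parameters
    z <- (expr[std_i$params$gene_id, i] - std_i$params$mean) /
      std_i$params$sd
    pred <- predict_bccp(fit, matrix(z, ncol = 1,
                                     dimnames = list(std_i$params$gene_id,
                                                     colnames(expr)[i])))
    evaluated <- evaluated + 1L
    if (pred$risk != risk[i]) errors <- errors + 1L
  }
  if (skipped > 0L) warning(skipped, " LOOCV fold(s) skipped")
  if (evaluated == 0L) stop("no evaluable LOOCV folds")
  structure(errors / evaluated, n_folds = evaluated, n_skipped = skipped)
}

#' @export
print.fatsig_bccp <- function(x, ...) {
  cat("BCCP model:", length(x$gene_ids), "genes; class means",
      sprintf("LR %.3f / HR %.3f", x$mu_lr, x$mu_hr),
      sprintf("; pooled SD %.3f\n", x$pooled_sd))
  invisible(x)
}
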