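.file_digests <- function(paths) {
  md5 <- tools::md5sum(paths)
  stats::setNames(as.vector(md5), basename(paths))
}

.manifest <- function(stage, seed, paths, params, warnings = character()) {
  list(stage = stage,
       package_version = as.character(utils::packageVersion("fatsig")),
       seed = seed,
       params = params,
       outputs = .file_digests(paths),
       warnings = warnings)
}

#' Discovery run: derive, stratify, train and evaluate on one cohort
#'
#' Executes the training arm end to end on an aligned cohort: signature
#' selection by the four criteria, two-way clustering of patients on the
#' signature genes, LR/HR labeling, within-cohort standardization, BCCP
#' fitting with leave-one-out misclassification, and the five-year
#' overall-survival comparison of the two labeled subgroups. All artifacts
#' are written as TSV/JSON under `out_dir` with a JSON run manifest of
#' content digests.
#'
#' When the selection returns fewer than two genes there is nothing to
#' cluster on; the run returns early with `status = "no_signal"`.
#'
#' @param expr log2 expression matrix (genes x samples).
#' @param clinical clinical table (see [read_clinical()] for columns).
#' @param mutation mutation table (`sample_id`, `mutated`).
#' @param anchor anchor gene ID.
#' @param out_dir output directory.
#' @param thresholds selection thresholds, see [default_thresholds()].
#' @param priors BCCP priors, see [fit_bccp()].
#' @param horizon follow-up horizon in months for the survival report.
#' @param seed integer seed recorded in the manifest (the discovery run is
#'   deterministic; the seed exists so reruns are traceable).
#' @return list with `status`, `signature`, `labels`, `model`,
#'   `loocv_error`, `survival`, `manifest`.
#' @export
run_discovery <- function(expr, clinical, mutation, anchor, out_dir,
                          thresholds = default_thresholds(),
                          priors = c(0.5, 0.5), horizon = 60, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warns <- character()
  wh <- function(expr_call) {
    withCallingHandlers(expr_call, warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  aligned <- align_cohort(expr, clinical, mutation)

  sig <- wh(select_signature(aligned$expression, aligned$mutation, anchor,
                             thresholds = thresholds))
  sig_path <- file.path(out_dir, "signature.json")
  write_signature(sig, sig_path)
  if (nrow(sig$genes) < 2L) {
    manifest <- .manifest("discovery", seed, sig_path,
                          list(anchor = anchor, thresholds = thresholds),
                          c(warns, "no signal: fewer than 2 signature genes"))
    man_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = I(17))
    return(list(status = "no_signal", signature = sig, labels = NULL,
                model = NULL, loocv_error = NULL, survival = NULL,
                manifest = manifest))
  }

  sig_expr <- aligned$expression[sig$genes$gene_id, , drop = FALSE]
  dend <- wh(cluster_samples(sig_expr))
  labels <- assign_risk_labels(cut_two(dend), aligned$mutation,
                               aligned$expression, anchor)
  labels_path <- file.path(out_dir, "labels.tsv")
  write_table_tsv(labels, labels_path)

  std <- wh(standardize(aligned$expression))
  model <- wh(fit_bccp(std$expression, labels, sig, priors = priors))
  model_path <- file.path(out_dir, "bccp_model.json")
  write_bccp(model, model_path)
  cv <- wh(loocv_error(std$expression, labels, sig, priors = priors))

  surv <- survival_report(aligned$clinical, labels, endpoint = "os",
                          horizon = horizon)
  surv_path <- file.path(out_dir, "survival_os.tsv")
  .write_survival_report(surv, surv_path)

  paths <- c(sig_path, labels_path, model_path, surv_path)
  manifest <- .manifest("discovery", seed, paths,
                        list(anchor = anchor, thresholds = thresholds,
                             priors = priors, horizon = horizon,
                             loocv_error = as.numeric(cv)),
                        warns)
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = I(17))
  list(status = "ok", signature = sig, labels = labels, model = model,
       loocv_error = cv, survival = surv, manifest = manifest)
}

#' Validation run: transfer the classifier to independent cohorts
#'
#' For each cohort: within-cohort standardization, BCCP prediction of
#' LR/HR labels, and the five-year survival comparison of the predicted
#' subgroups, plus optional stratified analyses (e.g. by HPV status,
#' radiotherapy, or stage) given as `subsets`. Strata that leave fewer
#' than two risk groups (or no events) are skipped with a notice rather
#' than failing the run.
#'
#' @param model `fatsig_bccp` from [fit_bccp()] / [run_discovery()].
#' @param cohorts named list; each element a list with `expression`,
#'   `clinical` (and optionally `mutation`, unused here).
#' @param out_dir output directory.
#' @param endpoint survival endpoint for the per-cohort report.
#' @param horizon months of administrative censoring.
#' @param subsets list of named one-element lists, e.g.
#'   `list(list(hpv = "neg"), list(radiotherapy = "yes"))`.
#' @param seed integer seed recorded in the manifest.
#' @return list with per-cohort `labels`, `survival`, `subset_reports`,
#'   and the run `manifest`.
#' @export
run_validation <- function(model, cohorts, out_dir,
                           endpoint = "os", horizon = 60,
                           subsets = list(), seed = 1L) {
  stopifnot(inherits(model, "fatsig_bccp"), length(cohorts) >= 1L)
  if (is.null(names(cohorts))) {
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  warns <- character()
  results <- list()
  for (nm in names(cohorts)) {
    co <- cohorts[[nm]]
    std <- withCallingHandlers(standardize(co$expression),
                               warning = function(w) {
                                 warns <<- c(warns, conditionMessage(w))
                                 invokeRestart("muffleWarning")
                               })
    pred <- predict_bccp(model, std$expression)
    lp <- file.path(out_dir, paste0("labels_", nm, ".tsv"))
    write_table_tsv(pred, lp)
    surv <- survival_report(co$clinical, pred, endpoint = endpoint,
                            horizon = horizon)
    sp <- file.path(out_dir, paste0("survival_", nm, ".tsv"))
    .write_survival_report(surv, sp)
    subset_reports <- lapply(subsets, function(ss) {
      rep <- survival_report(co$clinical, pred, endpoint = endpoint,
                             horizon = horizon, subset = ss)
      if (rep$skipped) {
        warns <<- c(warns, paste0("subset ", names(ss), "=", ss[[1L]],
                                  " skipped in cohort ", nm))
      }
      rep
    })
    paths <- c(paths, lp, sp)
    results[[nm]] <- list(labels = pred, survival = surv,
                          subset_reports = subset_reports)
  }
  manifest <- .manifest("validation", seed, paths,
                        list(endpoint = endpoint, horizon = horizon,
                             n_cohorts = length(cohorts)),
                        warns)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17))
  results$manifest <- manifest
  results
}

.write_survival_report <- function(rep, path) {
  if (isTRUE(rep$skipped)) {
    df <- data.frame(n = rep$n, skipped = TRUE)
  } else {
    df <- data.frame(n = rep$n, chi2 = rep$logrank$chi2,
                     df = rep$logrank$df, p = rep$logrank$p,
                     t(rep$five_year), skipped = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

BCCP_SCHEMA_VERSION <- "1.0"

#' Serialize / load a BCCP model as JSON
#'
#' @param model `fatsig_bccp` model.
#' @param path file path.
#' @export
write_bccp <- function(model, path) {
  stopifnot(inherits(model, "fatsig_bccp"))
  obj <- list(schema_version = BCCP_SCHEMA_VERSION,
              gene_ids = model$gene_ids,
              weights = as.numeric(model$weights),
              mu_lr = model$mu_lr, mu_hr = model$mu_hr,
              pooled_sd = model$pooled_sd,
              priors = as.numeric(model$priors),
              decision_threshold = model$decision_threshold,
              missing_genes = model$missing_genes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_bccp
#' @return `read_bccp()` returns the `fatsig_bccp` model.
#' @export
read_bccp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema_version, BCCP_SCHEMA_VERSION)) {
    stop("BCCP model schema version mismatch")
  }
  structure(list(gene_ids = obj$gene_ids,
                 weights = stats::setNames(obj$weights, obj$gene_ids),
                 mu_lr = obj$mu_lr, mu_hr = obj$mu_hr,
                 pooled_sd = obj$pooled_sd,
                 priors = stats::setNames(obj$priors, c("LR", "HR")),
                 decision_threshold = obj$decision_threshold,
                 missing_genes = obj$missing_genes),
            class = "fatsig_bccp")
}
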