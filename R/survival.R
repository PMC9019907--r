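#' Administrative censoring at a follow-up horizon
#'
#' Times beyond the horizon are set to the horizon with the event flag
#' cleared — the "five-year" framing (60 months) of survival comparisons.
#'
#' @param samples data.frame with `time` and `event` columns.
#' @param horizon months, > 0 (default 60 = five years).
#' @return the data.frame with truncated `time`/`event`.
#' @export
truncate_horizon <- function(samples, horizon = 60) {
  stopifnot(horizon > 0, all(c("time", "event") %in% colnames(samples)))
  over <- samples$time > horizon
  samples$event[over] <- 0L
  samples$time[over] <- horizon
  samples
}

#' Kaplan-Meier product-limit estimate
#'
#' @param samples data.frame with `time`, `event`.
#' @return data.frame with `time` (distinct event/censoring times),
#'   `n_risk`, `n_event`, `surv` and Greenwood `se`.
#' @export
km_estimate <- function(samples) {
  stopifnot(nrow(samples) >= 1L)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = samples)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv, se = fit$std.err * fit$surv)
}

#' Survival probability at a time point
#'
#' Reads `S(t)` off a Kaplan-Meier curve (step function, right-continuous).
#'
#' @param km curve from [km_estimate()].
#' @param t time point in months.
#' @return estimated survival probability.
#' @export
km_at <- function(km, t) {
  idx <- which(km$time <= t & km$n_event > 0)
  if (!length(idx)) return(1)
  km$surv[max(idx)]
}

#' Log-rank test between survival groups
#'
#' Standard log-rank statistic (observed minus expected under the
#' hypergeometric distribution at each event time), chi-squared with
#' `g - 1` degrees of freedom.
#'
#' @param samples data.frame with `time`, `event`.
#' @param group group label per row (>= 2 groups).
#' @return list with `chi2`, `df`, `p`.
#' @export
logrank_test <- function(samples, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L) {
    stop("log-rank test needs >= 2 groups")
  }
  if (sum(samples$event) == 0L) {
    warning("no events; log-rank p set to 1")
    return(list(chi2 = 0, df = nlevels(droplevels(group)) - 1L, p = 1))
  }
  df <- data.frame(time = samples$time, event = samples$event,
                   group = droplevels(group))
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  dfree <- length(fit$n) - 1L
  list(chi2 = fit$chisq, df = dfree,
       p = stats::pchisq(fit$chisq, dfree, lower.tail = FALSE))
}

#' Univariate or multivariate Cox proportional-hazards fit
#'
#' Wraps `survival::coxph` with Breslow tie handling (Efron via `ties`),
#' complete-case rows, and Wald confidence intervals
#' `exp(beta +/- 1.96 se)`. In univariate mode each covariate is fit
#' alone; in multivariate mode all are fit jointly.
#'
#' @param samples data.frame with `time`, `event`.
#' @param covariates data.frame of covariates, same row order.
#' @param multivariate fit all covariates jointly.
#' @param ties tie method, `"breslow"` (default) or `"efron"`.
#' @return data.frame with one row per covariate level contrast: `term`,
#'   `hr`, `ci_lower`, `ci_upper`, `p`, `loglik`, `n`.
#' @export
cox_fit <- function(samples, covariates, multivariate = FALSE,
                    ties = "breslow") {
  stopifnot(nrow(samples) == nrow(covariates))
  base <- data.frame(time = samples$time, event = samples$event)
  fit_one <- function(dat) {
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    nev <- sum(dat$event)
    nco <- ncol(dat) - 2L
    if (nev < nco) stop("fewer events (", nev, ") than covariates (",
                        nco, ")")
    fit <- survival::coxph(
      survival::Surv(time, event) ~ .,
      data = dat, ties = ties,
      control = survival::coxph.control(iter.max = 50)
    )
    if (!is.null(fit$info) && !fit$info == 0) stop("Cox fit did not converge")
    s <- summary(fit)
    co <- s$coefficients
    data.frame(term = rownames(co),
               hr = co[, "exp(coef)"],
               ci_lower = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
               ci_upper = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
               p = co[, "Pr(>|z|)"],
               loglik = fit$loglik[2L],
               n = s$n,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  if (multivariate) {
    fit_one(cbind(base, covariates))
  } else {
    out <- lapply(colnames(covariates), function(v) {
      fit_one(cbind(base, covariates[, v, drop = FALSE]))
    })
    do.call(rbind, out)
  }
}

#' Risk-by-treatment interaction test
#'
#' Cox model with both main effects and their product; returns the Wald
#' p-value of the product term. All four cells of the 2x2 factor table
#' must be populated.
#'
#' @param samples data.frame with `time`, `event`.
#' @param factor_a,factor_b two-level factors per row (e.g., risk label and
#'   treatment flag).
#' @return list with `p` (Wald p of the interaction), `hr_interaction`,
#'   and the fitted coefficient table.
#' @export
interaction_test <- function(samples, factor_a, factor_b) {
  a <- droplevels(as.factor(factor_a))
  b <- droplevels(as.factor(factor_b))
  tab <- table(a, b)
  if (any(tab == 0L)) {
    empty <- which(tab == 0L, arr.ind = TRUE)
    stop("empty cell(s) in interaction table: ",
         paste(apply(empty, 1L, function(rc) {
           paste0(rownames(tab)[rc[1L]], " x ", colnames(tab)[rc[2L]])
         }), collapse = ", "))
  }
  if (sum(samples$event) < 1L) stop("interaction test needs >= 1 event")
  dat <- data.frame(time = samples$time, event = samples$event,
                    a = a, b = b)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  fit <- survival::coxph(survival::Surv(time, event) ~ a * b, data = dat,
                         ties = "breslow")
  co <- summary(fit)$coefficients
  int_row <- grep(":", rownames(co))
  list(p = co[int_row, "Pr(>|z|)"],
       hr_interaction = co[int_row, "exp(coef)"],
       coefficients = co)
}

#' ROC curve, AUC and Youden-index threshold
#'
#' AUC by the trapezoidal rule (equivalently the normalized Mann-Whitney
#' statistic) with a DeLong 95% CI; the reported threshold maximizes the
#' Youden index `sensitivity + specificity - 1`, ties broken toward higher
#' sensitivity.
#'
#' @param scores numeric predictor (higher = more likely positive by
#'   default; orientation is resolved to keep AUC >= 0.5 reporting off —
#'   direction is fixed as `controls < cases`).
#' @param truth binary 0/1 (or two-level factor) class labels.
#' @return list with `auc`, `ci` (length 2), `threshold`, `sensitivity`,
#'   `specificity`, `youden`.
#' @export
roc_auc_youden <- function(scores, truth) {
  truth <- as.integer(as.factor(truth)) - 1L
  if (length(unique(truth)) < 2L) stop("both classes must be present")
  roc <- pROC::roc(response = truth, predictor = scores,
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- as.numeric(suppressWarnings(pROC::ci.auc(roc, method = "delong")))
  coords <- pROC::coords(roc, x = "all", ret = c("threshold",
                                                 "sensitivity",
                                                 "specificity"),
                         transpose = FALSE)
  youden <- coords$sensitivity + coords$specificity - 1
  best <- which(youden >= max(youden) - 1e-12)
  best <- best[which.max(coords$sensitivity[best])]
  list(auc = as.numeric(pROC::auc(roc)),
       ci = ci[c(1L, 3L)],
       threshold = coords$threshold[best],
       sensitivity = coords$sensitivity[best],
       specificity = coords$specificity[best],
       youden = youden[best])
}

#' Subgroup survival report
#'
#' The figure-style machinery: Kaplan-Meier five-year comparison of risk
#' subgroups, optionally within a clinical stratum (e.g., HPV-negative
#' patients, radiotherapy-treated patients, advanced stage), using
#' complete cases for the stratum variable.
#'
#' @param clinical clinical data.frame with survival columns.
#' @param labels risk-label data.frame (`sample_id`, `risk`).
#' @param endpoint `"os"` or `"rfs"`.
#' @param horizon months of administrative censoring (NULL = none).
#' @param subset optional named one-element list, e.g.
#'   `list(hpv = "neg")`, restricting to a stratum.
#' @return list with `n`, `logrank` (chi2/df/p), `five_year` survival per
#'   risk group, and `skipped` (TRUE when the subset left fewer than two
#'   groups or no events).
#' @export
survival_report <- function(clinical, labels, endpoint = c("os", "rfs"),
                            horizon = 60, subset = NULL) {
  endpoint <- match.arg(endpoint)
  tcol <- paste0(endpoint, "_months")
  ecol <- paste0(endpoint, "_event")
  df <- merge(clinical, labels[, c("sample_id", "risk")], by = "sample_id")
  if (!is.null(subset)) {
    stopifnot(length(subset) == 1L, !is.null(names(subset)))
    var <- names(subset)
    if (!var %in% colnames(df)) {
      stop("subset column '", var, "' not present in clinical table")
    }
    df <- df[!is.na(df[[var]]) & df[[var]] == subset[[1L]], , drop = FALSE]
  }
  df <- df[!is.na(df[[tcol]]) & !is.na(df[[ecol]]), , drop = FALSE]
  samples <- data.frame(time = df[[tcol]], event = df[[ecol]])
  if (!is.null(horizon)) samples <- truncate_horizon(samples, horizon)
  if (length(unique(df$risk)) < 2L || sum(samples$event) == 0L) {
    return(list(n = nrow(df), logrank = NULL, five_year = NULL,
                skipped = TRUE))
  }
  lr <- logrank_test(samples, df$risk)
  fy <- vapply(split(samples, df$risk), function(s) {
    km_at(km_estimate(s), 60)
  }, numeric(1))
  list(n = nrow(df), logrank = lr, five_year = fy, skipped = FALSE)
}
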