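# Independent brute-force oracles used to cross-check the implementation.

# Exhaustive permutation p-value for the two-sample pooled-t statistic:
# fraction of group relabelings whose |t| is at least the observed |t|.
perm_t_p <- function(x, y) {
  pooled_t <- function(a, b) {
    n1 <- length(a); n0 <- length(b)
    sp2 <- ((n1 - 1) * var(a) + (n0 - 1) * var(b)) / (n1 + n0 - 2)
    (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n0))
  }
  z <- c(x, y)
  n1 <- length(x)
  obs <- abs(pooled_t(x, y))
  idx <- utils::combn(length(z), n1)
  stat <- apply(idx, 2, function(i) abs(pooled_t(z[i], z[-i])))
  mean(stat >= obs - 1e-12)
}

# Pearson correlation from the raw covariance / sigma*sigma definition.
brute_cor <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# AUC by exhaustive concordant-pair counting (ties count 1/2).
brute_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Complete-linkage merge heights recomputed from scratch at every step:
# clusters are kept as member lists and the inter-cluster distance is the
# max over all member pairs of the original distance matrix.
brute_complete_heights <- function(d) {
  n <- ncol(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        dij <- max(d[clusters[[i]], clusters[[j]]])
        if (dij < best) { best <- dij; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# Kaplan-Meier by the hand product-limit table over distinct event times.
brute_km <- function(time, event, at) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  for (tt in ts[ts <= at]) {
    n_risk <- sum(time >= tt)
    d <- sum(time == tt & event == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}

# Two-group log-rank chi-square from the O-E / hypergeometric-variance sums.
brute_logrank_chi2 <- function(time, event, group) {
  g1 <- levels(factor(group))[1]
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (tt in ts) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & group == g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Leave-one-out misclassification by an explicit fold loop written from
# first principles (pooled-t weights, Gaussian class model, Bayes rule).
brute_loocv <- function(m, risk, priors = c(0.5, 0.5)) {
  n <- ncol(m)
  errs <- 0
  for (i in seq_len(n)) {
    tr <- m[, -i, drop = FALSE]
    rr <- risk[-i]
    w <- apply(tr, 1, function(v) {
      a <- v[rr == "HR"]; b <- v[rr == "LR"]
      sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
        (length(a) + length(b) - 2)
      (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    })
    cc <- as.vector(w %*% tr)
    mu_hr <- mean(cc[rr == "HR"]); mu_lr <- mean(cc[rr == "LR"])
    sd_p <- sqrt((sum((cc[rr == "HR"] - mu_hr)^2) +
                    sum((cc[rr == "LR"] - mu_lr)^2)) / (length(cc) - 2))
    c0 <- sum(w * m[, i])
    post <- priors[2] * dnorm(c0, mu_hr, sd_p) /
      (priors[2] * dnorm(c0, mu_hr, sd_p) +
         priors[1] * dnorm(c0, mu_lr, sd_p))
    if ((if (post > 0.5) "HR" else "LR") != risk[i]) errs <- errs + 1
  }
  errs / n
}

# Small planted cohort for cheap end-to-end checks.
small_cfg <- function(seed = 1, n_samples = 150L, n_genes = 120L,
                      n_signature = 10L, ...) {
  sim_config(n_samples = n_samples, n_genes = n_genes,
             n_signature = n_signature, seed = seed, ...)
}

null_cfg <- function(seed = 1, n_samples = 120L, n_genes = 60L,
                     n_signature = 5L) {
  sim_config(n_samples = n_samples, n_genes = n_genes,
             n_signature = n_signature,
             delta_log2 = 0, rho = 0, group_shift_log2 = 0,
             mut_anchor_shift = 0, hr_hazard_ratio = 1,
             rt_hazard_ratio = 1, interaction_effect = 1,
             platform_shift_sd = 0, platform_scale_sd = 0, seed = seed)
}

# Random risk-label frame for classifier fixtures.
label_frame <- function(ids, risk) {
  data.frame(sample_id = ids, risk = risk, stringsAsFactors = FALSE)
}
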