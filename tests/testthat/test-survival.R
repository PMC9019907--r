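surv_frame <- function(time, event) data.frame(time = time, event = event)

test_that("administrative truncation follows its definition", {
  s <- truncate_horizon(surv_frame(c(70, 59, 60), c(1, 1, 1)), 60)
  expect_equal(s$time, c(60, 59, 60))
  expect_equal(s$event, c(0, 1, 1))
  expect_error(truncate_horizon(surv_frame(1, 1), -5))
})

test_that("KM matches hand product-limit tables", {
  # no events: S = 1 everywhere
  km <- km_estimate(surv_frame(c(5, 10, 15), c(0, 0, 0)))
  expect_true(all(km$surv == 1))

  # all events, no censoring: empirical survival
  km <- km_estimate(surv_frame(c(1, 2, 3), c(1, 1, 1)))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))

  # censoring fixture 1+, 2, 3+, 4: S(2) = 2/3, S(4) = 0
  km <- km_estimate(surv_frame(c(1, 2, 3, 4), c(0, 1, 0, 1)))
  expect_equal(km_at(km, 2), 2 / 3, tolerance = 1e-12)
  expect_equal(km_at(km, 4), 0)
  expect_equal(km_at(km, 1.5), 1)
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(31)
  t <- round(rexp(60, 0.05), 1)
  km <- km_estimate(surv_frame(t, rep(1, 60)))
  for (q in c(5, 15, 40)) {
    expect_equal(km_at(km, q), mean(t > q), tolerance = 1e-12)
    expect_equal(km_at(km, q), brute_km(t, rep(1, 60), q),
                 tolerance = 1e-12)
  }
})

test_that("KM curves are monotone with S(0) = 1 and truncation-stable", {
  set.seed(32)
  t <- rexp(80, 0.02)
  e <- rbinom(80, 1, 0.7)
  km <- km_estimate(surv_frame(t, e))
  expect_true(all(diff(km$surv) <= 1e-12))
  expect_true(all(km$surv >= 0 & km$surv <= 1))
  expect_equal(km_at(km, 0), 1)
  trunc <- truncate_horizon(surv_frame(t, e), 60)
  expect_equal(km_at(km_estimate(trunc), 60), km_at(km, 60),
               tolerance = 1e-12)
})

test_that("log-rank handles degenerate and symmetric inputs", {
  s <- surv_frame(c(1, 2, 3, 1, 2, 3), c(1, 0, 1, 1, 0, 1))
  res <- logrank_test(s, rep(c("a", "b"), each = 3))
  expect_equal(res$chi2, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)
  expect_error(logrank_test(s, rep("a", 6)), "2 groups")
  expect_warning(
    res0 <- logrank_test(surv_frame(1:4, rep(0, 4)), c(1, 1, 2, 2)),
    "no events")
  expect_equal(res0$p, 1)
})

test_that("log-rank chi-square matches the hand O-E computation", {
  time <- c(3, 5, 7, 9, 11, 4, 6, 8)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1)
  group <- rep(c("x", "y"), c(5, 3))
  res <- logrank_test(surv_frame(time, event), group)
  expect_equal(res$chi2, brute_logrank_chi2(time, event, group),
               tolerance = 1e-10)
  expect_equal(res$p, pchisq(res$chi2, 1, lower.tail = FALSE))
})

test_that("log-rank is invariant to strictly monotone time transforms", {
  set.seed(33)
  t <- rexp(50, 0.05)
  e <- rbinom(50, 1, 0.6)
  g <- rep(c("a", "b"), 25)
  r1 <- logrank_test(surv_frame(t, e), g)
  r2 <- logrank_test(surv_frame(t^1.7 + 2, e), g)
  expect_equal(r2$chi2, r1$chi2, tolerance = 1e-10)
})

test_that("Cox fits are scale invariant and recover a null covariate", {
  set.seed(34)
  n <- 200
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.02 * 2^x)
  s <- surv_frame(pmin(t, 100), as.integer(t <= 100))
  cx1 <- cox_fit(s, data.frame(x = x))
  s2 <- s
  s2$time <- s2$time * 2
  cx2 <- cox_fit(s2, data.frame(x = x))
  expect_equal(cx2$hr, cx1$hr, tolerance = 1e-8)
  expect_true(cx1$ci_lower <= cx1$hr && cx1$hr <= cx1$ci_upper)

  # null covariate: Wald CI covers 1 at ~95%
  cover <- replicate(200, {
    t <- rexp(120, 0.02)
    z <- rbinom(120, 1, 0.5)
    cx <- cox_fit(surv_frame(pmin(t, 100), as.integer(t <= 100)),
                  data.frame(z = z))
    cx$ci_lower <= 1 && 1 <= cx$ci_upper
  })
  expect_gte(mean(cover), 0.9)
})

test_that("univariate and multivariate Cox modes differ as expected", {
  co <- simulate_cohort(small_cfg(seed = 36, n_samples = 250L), 0)
  cl <- co$clinical
  covs <- data.frame(
    risk = factor(co$truth_labels$group, levels = c("LR", "HR")),
    age_group = factor(cl$age_group),
    sex = factor(cl$sex)
  )
  s <- surv_frame(cl$os_months, cl$os_event)
  uni <- cox_fit(s, covs, multivariate = FALSE)
  multi <- cox_fit(s, covs, multivariate = TRUE)
  expect_equal(nrow(uni), nrow(multi))
  expect_gt(uni$hr[uni$term == "riskHR"], 1.2)
  expect_lt(uni$p[uni$term == "riskHR"], 0.05)
})

test_that("interaction test is invariant to factor relabeling and checks
           cells", {
  set.seed(37)
  n <- 300
  a <- rbinom(n, 1, 0.5)
  b <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.02 * 1.5^a * 0.8^b * 1.8^(a * b))
  s <- surv_frame(pmin(t, 120), as.integer(t <= 120))
  r1 <- interaction_test(s, ifelse(a == 1, "HR", "LR"),
                         ifelse(b == 1, "yes", "no"))
  r2 <- interaction_test(s, ifelse(a == 1, "zHigh", "aLow"),
                         ifelse(b == 1, "zYes", "aNo"))
  expect_equal(r2$p, r1$p, tolerance = 1e-8)
  expect_error(interaction_test(s, rep("HR", n),
                                ifelse(b == 1, "yes", "no")))
  bad_a <- ifelse(a == 1, "HR", "LR")
  bad_a[b == 0 & a == 1] <- "LR"  # empty HR x no cell
  expect_error(interaction_test(s, bad_a, ifelse(b == 1, "yes", "no")),
               "empty cell")
})

test_that("a planted treatment-by-risk interaction is detected", {
  # generator interaction_effect = 0.4 at n = 600: the Wald test of the
  # product term rejects at alpha = 0.05 in well over half the replicates
  rej <- vapply(1:60, function(r) {
    co <- simulate_cohort(sim_config(n_samples = 600L, n_genes = 8L,
                                     n_signature = 3L,
                                     interaction_effect = 0.4,
                                     seed = 8000 + r), 0)
    s <- data.frame(time = co$clinical$os_months,
                    event = co$clinical$os_event)
    interaction_test(s, co$truth_labels$group,
                     co$clinical$radiotherapy)$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.5)
})

test_that("AUC equals exhaustive pair counting and Youden is coherent", {
  # perfect separation
  roc <- roc_auc_youden(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(roc$auc, 1)
  expect_equal(roc$youden, 1)

  # 6-point fixture with a tie
  scores <- c(0.1, 0.4, 0.35, 0.8, 0.4, 0.7)
  truth <- c(0, 0, 1, 1, 1, 0)
  roc <- roc_auc_youden(scores, truth)
  expect_equal(roc$auc, brute_auc(scores, truth), tolerance = 1e-12)
  expect_equal(roc$youden, roc$sensitivity + roc$specificity - 1,
               tolerance = 1e-12)

  # random fixtures: exact Mann-Whitney identity
  set.seed(38)
  for (i in 1:5) {
    sc <- sample(seq(0, 1, 0.05), 30, TRUE)
    tr <- rbinom(30, 1, 0.5)
    if (length(unique(tr)) < 2) next
    expect_equal(roc_auc_youden(sc, tr)$auc, brute_auc(sc, tr),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc_youden(1:5, rep(1, 5)), "both classes")
})

test_that("survival_report stratifies, truncates and skips empty strata", {
  co <- simulate_cohort(small_cfg(seed = 39, n_samples = 250L), 0)
  labels <- data.frame(sample_id = co$truth_labels$sample_id,
                       risk = co$truth_labels$group)
  rep_all <- survival_report(co$clinical, labels, endpoint = "os")
  expect_false(rep_all$skipped)
  expect_lt(rep_all$logrank$p, 0.05)
  expect_lt(rep_all$five_year[["HR"]], rep_all$five_year[["LR"]])

  rep_neg <- survival_report(co$clinical, labels, endpoint = "os",
                             subset = list(hpv = "neg"))
  expect_false(rep_neg$skipped)
  expect_lt(rep_neg$n, rep_all$n)

  cl2 <- co$clinical
  cl2$hpv <- "neg"
  rep_pos <- survival_report(cl2, labels, subset = list(hpv = "pos"))
  expect_true(rep_pos$skipped)
  expect_error(survival_report(co$clinical, labels,
                               subset = list(nope = "x")),
               "nope")
})
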