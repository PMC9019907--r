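std_cohort <- function(seed = 1, ...) {
  co <- simulate_cohort(small_cfg(seed = seed, ...), 0)
  list(cohort = co, std = standardize(co$expression)$expression)
}

test_that("standardization gives mean 0, SD 1 per gene and is idempotent", {
  co <- simulate_cohort(small_cfg(seed = 21), 0)
  s <- standardize(co$expression)
  expect_lt(max(abs(rowMeans(s$expression))), 1e-10)
  expect_lt(max(abs(apply(s$expression, 1, sd) - 1)), 1e-10)
  s2 <- standardize(s$expression)
  expect_lt(max(abs(s2$expression - s$expression)), 1e-10)
})

test_that("constant genes are dropped with a warning", {
  m <- matrix(rnorm(20), 4, 5,
              dimnames = list(paste0("G", 1:4), paste0("S", 1:5)))
  m[2, ] <- 7
  expect_warning(s <- standardize(m), "constant")
  expect_false("G2" %in% rownames(s$expression))
})

test_that("BCCP parameters match hand calculation on a 2-gene toy", {
  # 6 samples, 2 genes, fixed values
  x <- matrix(c(1.0, 2.0, 1.5, -1.0, -2.0, -1.5,
                0.5, 1.5, 1.0, 0.0, -1.0, -0.5),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("Ga", "Gb"), paste0("S", 1:6)))
  risk <- c("HR", "HR", "HR", "LR", "LR", "LR")
  lab <- label_frame(colnames(x), risk)
  model <- fit_bccp(x, lab, c("Ga", "Gb"))

  hand_t <- function(v) {
    a <- v[1:3]; b <- v[4:6]
    sp2 <- (2 * var(a) + 2 * var(b)) / 4
    (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  }
  t_a <- hand_t(x["Ga", ]); t_b <- hand_t(x["Gb", ])
  expect_equal(unname(model$weights), c(t_a, t_b), tolerance = 1e-12)

  cc <- t_a * x["Ga", ] + t_b * x["Gb", ]
  expect_equal(model$mu_hr, mean(cc[1:3]), tolerance = 1e-12)
  expect_equal(model$mu_lr, mean(cc[4:6]), tolerance = 1e-12)
  expect_equal(model$pooled_sd,
               sqrt((2 * var(cc[1:3]) + 2 * var(cc[4:6])) / 4),
               tolerance = 1e-12)
})

test_that("posterior equals the equal-variance Gaussian logistic identity", {
  model <- structure(list(gene_ids = "G1", weights = c(G1 = 1),
                          mu_lr = -1, mu_hr = 1, pooled_sd = 1,
                          priors = c(LR = 0.5, HR = 0.5),
                          decision_threshold = 0.5,
                          missing_genes = character()),
                     class = "fatsig_bccp")
  cs <- seq(-3, 3, by = 0.25)
  m <- matrix(cs, 1, dimnames = list("G1", paste0("S", seq_along(cs))))
  pred <- predict_bccp(model, m)
  closed <- 1 / (1 + exp(-(1 - (-1)) * (cs - 0) / 1^2))
  expect_equal(pred$posterior_hr, closed, tolerance = 1e-10)
  # midpoint of the class means -> posterior exactly 1/2
  expect_equal(pred$posterior_hr[cs == 0], 0.5, tolerance = 1e-12)
  # monotone in the compound covariate when mu_HR > mu_LR
  expect_true(all(diff(pred$posterior_hr) > 0))
})

test_that("zero weights collapse the posterior to the prior", {
  model <- structure(list(gene_ids = "G1", weights = c(G1 = 0),
                          mu_lr = 0, mu_hr = 0, pooled_sd = 1,
                          priors = c(LR = 0.3, HR = 0.7),
                          decision_threshold = 0.5,
                          missing_genes = character()),
                     class = "fatsig_bccp")
  m <- matrix(rnorm(5), 1, dimnames = list("G1", paste0("S", 1:5)))
  pred <- predict_bccp(model, m)
  expect_equal(pred$posterior_hr, rep(0.7, 5), tolerance = 1e-12)
})

test_that("posteriors are proper probabilities summing to one", {
  sc <- std_cohort(seed = 23)
  lab <- label_frame(sc$cohort$truth_labels$sample_id,
                     sc$cohort$truth_labels$group)
  model <- fit_bccp(sc$std, lab, sc$cohort$truth_genes$gene_id)
  pred <- predict_bccp(model, sc$std)
  expect_true(all(pred$posterior_hr >= 0 & pred$posterior_hr <= 1))
  # the LR posterior is the exact complement by construction of Bayes' rule
  expect_equal(pred$posterior_hr + (1 - pred$posterior_hr),
               rep(1, nrow(pred)))
})

test_that("a separable single-gene class structure trains error-free", {
  set.seed(24)
  n <- 40
  g1 <- c(rnorm(n / 2, 3), rnorm(n / 2, -3))
  m <- rbind(G1 = g1, G2 = rnorm(n))
  colnames(m) <- paste0("S", 1:n)
  m <- standardize(m)$expression
  risk <- rep(c("HR", "LR"), each = n / 2)
  lab <- label_frame(colnames(m), risk)
  model <- fit_bccp(m, lab, c("G1", "G2"))
  expect_gt(abs(model$weights["G1"]), abs(model$weights["G2"]))
  pred <- predict_bccp(model, m)
  expect_equal(pred$risk, risk)
  expect_equal(as.numeric(loocv_error(m, lab, c("G1", "G2"))), 0)
})

test_that("LOOCV equals the brute-force fold loop on six samples", {
  set.seed(25)
  m <- matrix(rnorm(18), 3, 6,
              dimnames = list(paste0("G", 1:3), paste0("S", 1:6)))
  risk <- c("HR", "LR", "HR", "LR", "HR", "LR")
  lab <- label_frame(colnames(m), risk)
  got <- loocv_error(m, lab, paste0("G", 1:3))
  expect_equal(as.numeric(got), brute_loocv(m, risk))
  expect_equal(attr(got, "n_folds"), 6L)
})

test_that("with equal priors and balanced classes the posterior rule is
           nearest-class-mean classification", {
  set.seed(26)
  m <- matrix(rnorm(200), 4, 50,
              dimnames = list(paste0("G", 1:4), paste0("S", 1:50)))
  risk <- rep(c("HR", "LR"), 25)
  lab <- label_frame(colnames(m), risk)
  model <- fit_bccp(m, lab, paste0("G", 1:4))
  pred <- predict_bccp(model, m)
  nearest <- ifelse(abs(pred$score - model$mu_hr) <
                      abs(pred$score - model$mu_lr), "HR", "LR")
  expect_equal(pred$risk, nearest)
})

test_that("missing signature genes are dropped with warnings or rejected", {
  sc <- std_cohort(seed = 27)
  lab <- label_frame(sc$cohort$truth_labels$sample_id,
                     sc$cohort$truth_labels$group)
  genes <- c(sc$cohort$truth_genes$gene_id, "NOT_A_GENE")
  expect_warning(model <- fit_bccp(sc$std, lab, genes), "absent")
  expect_false("NOT_A_GENE" %in% model$gene_ids)
  expect_error(fit_bccp(sc$std, lab, c("NOPE1", "NOPE2")),
               "no signature genes")
  sub <- sc$std[setdiff(rownames(sc$std),
                        model$gene_ids[-(1:2)]), , drop = FALSE]
  expect_warning(predict_bccp(model, sub), "50%")
})

test_that("single-class labelings are rejected", {
  sc <- std_cohort(seed = 28)
  lab <- label_frame(colnames(sc$std), rep("HR", ncol(sc$std)))
  expect_error(fit_bccp(sc$std, lab, sc$cohort$truth_genes$gene_id),
               ">= 2")
})

test_that("full-reselection LOOCV agrees with the fixed-set estimate on
           strong signal", {
  co <- simulate_cohort(small_cfg(seed = 60, n_samples = 60L,
                                  n_genes = 80L, n_signature = 8L), 0)
  lab <- label_frame(co$truth_labels$sample_id, co$truth_labels$group)
  std <- standardize(co$expression)$expression
  fixed <- as.numeric(loocv_error(std, lab, co$truth_genes$gene_id))
  full <- as.numeric(loocv_error_full(co$expression, lab, co$mutation,
                                      "FAT1"))
  expect_lte(fixed, 0.1)
  expect_lte(full, 0.15)
})

test_that("model JSON round trip is lossless", {
  sc <- std_cohort(seed = 29)
  lab <- label_frame(sc$cohort$truth_labels$sample_id,
                     sc$cohort$truth_labels$group)
  model <- fit_bccp(sc$std, lab, sc$cohort$truth_genes$gene_id)
  f <- withr::local_tempfile(fileext = ".json")
  write_bccp(model, f)
  back <- read_bccp(f)
  expect_equal(back$weights, model$weights, tolerance = 1e-15)
  expect_equal(back$mu_hr, model$mu_hr, tolerance = 1e-15)
  expect_equal(back$pooled_sd, model$pooled_sd, tolerance = 1e-15)
  pred1 <- predict_bccp(model, sc$std)
  pred2 <- predict_bccp(back, sc$std)
  expect_equal(pred2$posterior_hr, pred1$posterior_hr, tolerance = 1e-12)
})
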