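test_that("identical groups give p = 1 and fold change 1", {
  m <- matrix(rep(c(10, 20, 30), 6), nrow = 3)
  fm <- make_fm(m, groups = rep(c("PD", "control"), each = 3))
  res <- t_test_features(fm)
  expect_equal(res$t_p, rep(1, 3))
  expect_equal(res$fold_change, rep(1, 3))
  expect_false(any(res$significant))
})

test_that("ANOVA p equals the Welch t-test p for two groups", {
  set.seed(51)
  m <- matrix(rlnorm(200, log(1e4), 0.5), nrow = 10)
  fm <- make_fm(m, groups = rep(c("PD", "control"), each = 10))
  res <- t_test_features(fm)
  expect_equal(res$anova_p, res$t_p, tolerance = 1e-10)
})

test_that("type-I error is calibrated near the nominal 5%", {
  set.seed(52)
  n_feat <- 2000
  m <- matrix(rlnorm(n_feat * 40, log(1e4), 0.5), nrow = n_feat)
  fm <- make_fm(m, groups = rep(c("PD", "control"), each = 20))
  res <- t_test_features(fm)
  rate <- mean(res$t_p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("a 2x effect at the study conditions is detected with high power", {
  set.seed(53)
  n_feat <- 200
  pd <- matrix(rlnorm(n_feat * 20, log(2e4), 0.5), nrow = n_feat)
  ct <- matrix(rlnorm(n_feat * 20, log(1e4), 0.5), nrow = n_feat)
  fm <- make_fm(cbind(pd, ct), groups = rep(c("PD", "control"), each = 20))
  res <- t_test_features(fm)
  expect_gt(mean(res$t_p < 0.05), 0.9)
  expect_gt(mean(res$fold_change), 1.8)
  expect_error(t_test_features(make_fm(cbind(pd[, 1, drop = FALSE], ct),
                                       groups = c("PD", rep("control", 20)))),
               "at least 2")
})

test_that("Bayesian posterior finds strong effects and is seed-stable", {
  set.seed(54)
  n_feat <- 20
  pd <- matrix(rlnorm(n_feat * 10, log(4e4), 0.2), nrow = n_feat)
  ct <- matrix(rlnorm(n_feat * 10, log(1e4), 0.2), nrow = n_feat)
  fm <- make_fm(cbind(pd, ct), groups = rep(c("PD", "control"), each = 10))
  res <- bayes_upregulation(fm, bayes_config(seed = 7))
  expect_true(all(res$probability_up > 0.99))
  expect_true(all(res$flag == "ok"))
  expect_true(all(res$ci_low <= res$log_fold_change &
                    res$log_fold_change <= res$ci_high))
  expect_equal(res$probability_up + res$probability_down, rep(1, n_feat))
  # ln(4) effect sits inside the credible interval for most features
  expect_gt(mean(res$ci_low < log(4) & log(4) < res$ci_high), 0.8)
  # identical under the same seed
  res2 <- bayes_upregulation(fm, bayes_config(seed = 7))
  expect_identical(res, res2)
})

test_that("label permutation centers probability_up on one half", {
  set.seed(55)
  m <- matrix(rlnorm(50 * 20, log(1e4), 0.5), nrow = 50)
  fm <- make_fm(m, groups = rep(c("PD", "control"), each = 10))
  res <- bayes_upregulation(fm, bayes_config(seed = 3))
  expect_gt(mean(res$probability_up), 0.35)
  expect_lt(mean(res$probability_up), 0.65)
})

test_that("probability_up is monotone in the planted effect size", {
  set.seed(56)
  mean_p <- vapply(c(0, 0.5, 1, 2), function(l2fc) {
    pd <- matrix(rlnorm(30 * 12, log(1e4) + log(2) * l2fc, 0.5), nrow = 30)
    ct <- matrix(rlnorm(30 * 12, log(1e4), 0.5), nrow = 30)
    fm <- make_fm(cbind(pd, ct), groups = rep(c("PD", "control"), each = 12))
    mean(bayes_upregulation(fm, bayes_config(seed = 2))$probability_up)
  }, numeric(1))
  expect_true(all(diff(mean_p) > 0))
  expect_lt(mean_p[1], 0.65)
  expect_gt(mean_p[4], 0.97)
})

test_that("with full reliability the posterior matches the frequentist ratio", {
  set.seed(57)
  pd <- matrix(rlnorm(15 * 15, log(3e4), 0.4), nrow = 15)
  ct <- matrix(rlnorm(15 * 15, log(1e4), 0.4), nrow = 15)
  fm <- make_fm(cbind(pd, ct), groups = rep(c("PD", "control"), each = 15))
  bay <- bayes_upregulation(fm, bayes_config(p_reliability = 1, seed = 5))
  freq_lfc <- unname(rowMeans(log(fm$intensity[, 1:15])) -
                       rowMeans(log(fm$intensity[, 16:30])))
  expect_true(all(bay$ci_low < freq_lfc & freq_lfc < bay$ci_high))
  expect_equal(bay$log_fold_change, freq_lfc, tolerance = 0.15)
})

test_that("all-zero features are flagged, not crashed, and zeros censored", {
  set.seed(58)
  m <- matrix(rlnorm(5 * 12, log(1e4), 0.3), nrow = 5)
  m[1, ] <- 0                       # degenerate feature
  m[2, 1:3] <- 0                    # partially censored feature
  fm <- make_fm(m, groups = rep(c("PD", "control"), each = 6))
  res <- bayes_upregulation(fm, bayes_config(seed = 4))
  expect_equal(res$flag[1], "degenerate")
  expect_true(is.na(res$probability_up[1]))
  expect_equal(res$flag[2], "ok")
  expect_true(is.finite(res$log_fold_change[2]))
})

test_that("pseudo-standard QC passes nulls, fails planted effects, warns on missing", {
  set.seed(59)
  std_mz <- c(103.05, 105.07, 109.10)
  std_dt <- c(1.0, 1.0, 1.2)
  n <- 20
  base <- matrix(rlnorm(3 * 2 * n, log(5e4), 0.3), nrow = 3)
  other <- matrix(rlnorm(4 * 2 * n, log(1e4), 0.5), nrow = 4)
  groups <- rep(c("PD", "control"), each = n)
  fm <- make_fm(rbind(base, other), groups,
                mz = c(std_mz, 400, 500, 600, 700),
                drift_time = c(std_dt, 4, 5, 6, 7))
  qc <- qc_pseudo_standards(fm)
  expect_equal(qc$status, "PASS")
  expect_true(all(qc$standards$found))
  expect_true(is.finite(qc$biomass$group_p_value))
  # planted 3x effect on the standards
  fm_bad <- fm
  fm_bad$intensity[1:3, groups == "PD"] <-
    fm_bad$intensity[1:3, groups == "PD"] * 3
  expect_equal(qc_pseudo_standards(fm_bad)$status, "FAIL")
  # one standard absent
  fm_miss <- make_fm(rbind(base[1:2, ], other), groups,
                     mz = c(std_mz[1:2], 400, 500, 600, 700),
                     drift_time = c(std_dt[1:2], 4, 5, 6, 7))
  expect_equal(qc_pseudo_standards(fm_miss)$status, "WARN")
})
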