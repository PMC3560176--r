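test_that("ANCOVA gates covariates and adjusts values", {
  set.seed(7)
  n <- 100
  age <- rnorm(n, 30, 8)
  sex <- factor(sample(c("male", "female"), n, TRUE))
  group <- factor(rep(c("control", "ADHD"), each = n / 2),
                  levels = c("control", "ADHD"))
  # pure age effect, no group effect: group F stays small, age is gated in
  v <- 2 * age + rnorm(n)
  a <- ancova_adjust(v, group, age, sex)
  expect_true("age" %in% a$covariates_used)
  expect_lt(a$f_group, 4)
  expect_equal(length(a$adjusted_values), n)
  # adjusted values strip the age trend
  expect_lt(abs(cor(a$adjusted_values, age)), 0.15)
  # covariates independent of the value: adjustment is the identity
  v2 <- rnorm(n)
  a2 <- ancova_adjust(v2, group, age, sex)
  if (length(a2$covariates_used) == 0)
    expect_equal(a2$adjusted_values, v2)
  # equal group means give F near zero
  v3 <- c(rnorm(n / 2, 5), rnorm(n / 2, 5))
  expect_lt(ancova_adjust(v3, group, age, sex)$f_group, 5)
  expect_error(ancova_adjust(v[1:5], group[1:5], age[1:5], sex[1:5]), "10")
})

test_that("BH step-up q-values match hand-worked examples", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  # order preservation and monotone dominance
  p <- c(0.001, 0.9, 0.04, 0.2, 0.012)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_equal(order(q), order(p))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Cohen's d uses the pooled SD and brackets with its bootstrap CI", {
  x <- rnorm(60)
  expect_equal(cohens_d(x, x, n_boot = 50)$d, 0)
  expect_error(cohens_d(rep(1, 10), rep(1, 10)), "pooled")
  set.seed(2)
  a <- rnorm(60); b <- rnorm(40, 0.8)
  es <- cohens_d(a, b, seed = 3)
  sp <- sqrt((59 * var(a) + 39 * var(b)) / 98)
  expect_equal(es$d, (mean(b) - mean(a)) / sp, tolerance = 1e-12)
  expect_lte(es$ci_low, es$d + 0.05)
  expect_gte(es$ci_high, es$d - 0.05)
  expect_equal(es$n_boot, 1000)
})

test_that("summary-statistic d reproduces the printed movement effect size", {
  d <- cohens_d_from_summary(0.07, c(-0.001, 0.14), 60,
                             0.49, c(0.42, 0.57), 40)
  expect_equal(d, 1.587, tolerance = 1e-3)
  expect_equal(cohens_d_from_summary(5, c(4, 6), 50, 5, c(4, 6), 50), 0)
})

test_that("summary and raw-data d agree when summaries match", {
  set.seed(4)
  mk <- function(n, m, s) { x <- rnorm(n); m + s * (x - mean(x)) / sd(x) }
  a <- mk(60, 2, 0.5); b <- mk(40, 2.6, 0.7)
  ci_a <- mean(a) + c(-1, 1) * 1.96 * sd(a) / sqrt(60)
  ci_b <- mean(b) + c(-1, 1) * 1.96 * sd(b) / sqrt(40)
  expect_equal(cohens_d_from_summary(mean(a), ci_a, 60, mean(b), ci_b, 40),
               cohens_d(a, b, n_boot = 10)$d, tolerance = 1e-12)
})

test_that("trapezoidal AUC equals the exhaustive pair-counting oracle", {
  # toy sets including heavy ties
  sets <- list(
    list(s = c(1, 2, 3, 4, 5, 6, 1, 2, 2, 3, 3, 9),
         g = rep(c("ADHD", "control"), each = 6)),
    list(s = rep(c(0, 1), 6), g = rep(c("control", "ADHD"), each = 6)),
    list(s = rnorm(30), g = sample(rep(c("control", "ADHD"), 15))))
  set.seed(11)
  for (ts in sets) {
    r <- roc_auc(ts$s, ts$g)
    expect_equal(r$auc, auc_pair_oracle(ts$s, ts$g == "ADHD"), tolerance = 1e-12)
    expect_true(r$ci_low >= 0 && r$ci_high <= 1)
  }
  sep <- roc_auc(c(1, 2, 3, 10, 11, 12), rep(c("control", "ADHD"), each = 3))
  expect_equal(sep$auc, 1)
  expect_error(roc_auc(rnorm(5), rep("ADHD", 5)), "two classes")
})

test_that("orientation is fixed a priori, so anti-predictive scores stay below 0.5", {
  s <- c(5, 6, 7, 1, 2, 3)
  g <- rep(c("control", "ADHD"), each = 3)
  expect_equal(roc_auc(s, g)$auc, 0)
})

test_that("DeLong comparison behaves on degenerate and transformed scores", {
  set.seed(5)
  s <- c(rnorm(40), rnorm(60, 1))
  g <- rep(c("ADHD", "control"), c(40, 60))
  same <- delong_test(s, s, g)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  mono <- delong_test(s, exp(s) + 2, g)
  expect_equal(mono$auc_difference, 0)
  expect_equal(mono$z, 0)
  two <- delong_test(s, s + rnorm(100, 0, 0.8), g)
  expect_equal(sign(two$z), sign(two$auc_difference))
  expect_true(two$p > 0 && two$p <= 1)
})

test_that("DeLong z is calibrated under the null", {
  set.seed(6)
  zs <- replicate(150, {
    g <- rep(c("ADHD", "control"), c(40, 60))
    base <- rnorm(100, ifelse(g == "ADHD", 0.5, 0))
    s1 <- base + rnorm(100)
    s2 <- base + rnorm(100)
    delong_test(s1, s2, g)$z
  })
  expect_lt(abs(mean(zs)), 0.25)
  expect_lt(abs(sd(zs) - 1), 0.25)
})

test_that("binormal AUC links effect size and discrimination", {
  expect_equal(binormal_auc(0), 0.5)
  expect_equal(binormal_auc(1.6), 0.871, tolerance = 1e-3)
  d <- seq(-2, 3, by = 0.25)
  expect_true(all(diff(binormal_auc(d)) > 0))
  # empirical AUC of equal-variance normal samples converges to it
  set.seed(8)
  a <- rnorm(10000); b <- rnorm(10000, 1.0)
  emp <- roc_auc(c(a, b), rep(c("control", "ADHD"), each = 10000))$auc
  expect_lt(abs(emp - binormal_auc(1.0)), 0.01)
})

test_that("correlation CI matches the published rating correlation row", {
  ci <- correlation_ci_from_summary(0.54, 89)
  expect_lt(abs(ci[1] - 0.37), 0.01)
  expect_lt(abs(ci[2] - 0.68), 0.01)
  x <- rnorm(50)
  expect_equal(correlation_ci(x, x)$r, 1)
  set.seed(9)
  y <- rnorm(2000); x2 <- rnorm(2000)
  cc <- correlation_ci(x2, y)
  expect_lt(abs(cc$r), 0.08)
  expect_true(cc$ci_low < 0 && cc$ci_high > 0)
  expect_error(correlation_ci(rep(1, 10), rnorm(10)), "variance")
})

test_that("Welch t from summaries reproduces the group age comparison", {
  wt <- welch_t_from_summary(29, 9, 60, 35, 10, 40)
  expect_equal(wt$t, -3.06, tolerance = 0.01)
  expect_equal(wt$df, 77.5, tolerance = 1)
})

test_that("the discriminative index layers attention onto activity", {
  params <- group_parameters()
  calib <- sample_feature_cohort(params, 150, 150, seed = 71)
  eval_cohort <- sample_feature_cohort(params, 500, 500, seed = 72)
  idx <- fit_discriminative_index(calib)
  act <- fit_activity_composite(calib)
  dis <- fit_distraction_composite(calib)
  auc_idx <- roc_auc(apply_discriminative_index(idx, eval_cohort),
                     eval_cohort$group)$auc
  auc_act <- roc_auc(apply_activity_composite(act, eval_cohort),
                     eval_cohort$group)$auc
  auc_dis <- roc_auc(apply_distraction_composite(dis, eval_cohort),
                     eval_cohort$group)$auc
  expect_gte(auc_idx, auc_act - 0.02)
  expect_gte(auc_idx, auc_dis - 0.02)
  expect_gt(auc_act, auc_dis)
  # null features: no discrimination
  null_cohort <- calib
  for (m in c(feature_block("activity"), feature_block("no4s_attention")))
    null_cohort[[m]] <- rnorm(nrow(null_cohort))
  idx0 <- fit_discriminative_index(null_cohort)
  eval0 <- eval_cohort
  for (m in c(feature_block("activity"), feature_block("no4s_attention")))
    eval0[[m]] <- rnorm(nrow(eval0))
  auc0 <- roc_auc(apply_discriminative_index(idx0, eval0), eval0$group)$auc
  expect_lt(abs(auc0 - 0.5), 0.06)
})
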