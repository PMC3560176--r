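#' Covariate-adjusted group comparison (ANCOVA)
#'
#' Tests the group effect on a measure with age and sex as candidate
#' covariates.  Following the modeled study's rule, a covariate enters
#' the adjustment only when it significantly influences the dependent
#' variable on its own (unadjusted p < 0.05); the group F statistic is
#' the marginal (type II) F for group from the model containing the
#' gated covariates.  Adjusted values are the raw values minus the
#' centred covariate contributions, so they retain the grand mean and the
#' group effect.
#'
#' @param values Numeric dependent variable.
#' @param group Two-level factor (control/ADHD).
#' @param age,sex Covariates.
#' @param gate_p Covariate inclusion threshold (default 0.05).
#' @return List of class `ancova_result`: `f_group`, `p`,
#'   `adjusted_values`, `covariates_used`, `df`.
#' @export
ancova_adjust <- function(values, group, age, sex, gate_p = 0.05) {
  n <- length(values)
  stopifnot(length(group) == n, length(age) == n, length(sex) == n)
  if (n < 10) stop("need at least 10 observations")
  if (anyNA(values) || anyNA(age) || anyNA(sex)) stop("covariates must be complete")
  dat <- data.frame(values = values, group = factor(group),
                    age = age, sex = factor(sex))
  if (nlevels(dat$group) < 2) stop("group must have two levels")
  # covariate gate: marginal significance of each covariate alone
  p_age <- summary(lm(values ~ age, dat))$coefficients["age", 4]
  fit_sex <- lm(values ~ sex, dat)
  p_sex <- anova(fit_sex)[["Pr(>F)"]][1]
  use <- c(age = p_age < gate_p, sex = p_sex < gate_p)
  rhs <- paste(c("group", names(use)[use]), collapse = " + ")
  fit <- lm(as.formula(paste("values ~", rhs)), dat)
  if (fit$rank < length(coef(fit))) stop("rank-deficient design")
  dr <- drop1(fit, scope = ~group, test = "F")
  f_group <- dr[["F value"]][2]
  p <- dr[["Pr(>F)"]][2]
  adjusted <- values
  cf <- coef(fit)
  if (use["age"]) adjusted <- adjusted - cf["age"] * (dat$age - mean(dat$age))
  if (use["sex"]) {
    sex_num <- as.integer(dat$sex == levels(dat$sex)[2])
    cname <- paste0("sex", levels(dat$sex)[2])
    adjusted <- adjusted - cf[cname] * (sex_num - mean(sex_num))
  }
  structure(list(f_group = f_group, p = p,
                 adjusted_values = as.numeric(adjusted),
                 covariates_used = names(use)[use],
                 df = fit$df.residual),
            class = "ancova_result")
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up FDR adjustment: `q_i` is the minimum over ranks `j >= rank(i)`
#' of `m * p_(j) / j`, capped at 1 (delegated to
#' \code{stats::p.adjust(method = "BH")}).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values in the original order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Cohen's d with bootstrap confidence interval
#'
#' Standardized mean difference `(mean_b - mean_a) / s_pooled` with the
#' pooled standard deviation
#' `sqrt(((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2))`, and a
#' percentile bootstrap CI from `n_boot` resamples (drawn within group).
#' By convention group `b` is the case (ADHD) group, so positive d means
#' the case mean is higher.
#'
#' @param group_a,group_b Numeric samples (control, case).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed for the resampling.
#' @param conf Confidence level (default 0.95).
#' @return List of class `effect_size_result`: `d`, `ci_low`, `ci_high`,
#'   `n_boot`.
#' @export
cohens_d <- function(group_a, group_b, n_boot = 1000, seed = 1, conf = 0.95) {
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  d_of <- function(a, b) {
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
    (mean(b) - mean(a)) / sp
  }
  sp0 <- sqrt(((length(group_a) - 1) * var(group_a) +
                 (length(group_b) - 1) * var(group_b)) /
                (length(group_a) + length(group_b) - 2))
  if (!is.finite(sp0) || sp0 == 0) stop("pooled standard deviation is zero")
  d <- d_of(group_a, group_b)
  set.seed(seed)
  boots <- replicate(n_boot, d_of(sample(group_a, replace = TRUE),
                                  sample(group_b, replace = TRUE)))
  qs <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  structure(list(d = d, ci_low = qs[1], ci_high = qs[2], n_boot = n_boot),
            class = "effect_size_result")
}

#' Cohen's d from printed summary statistics
#'
#' Reconstructs per-group SDs from printed means and 95% CIs via
#' [reconstruct_sd_from_ci()] and applies the identical pooled-SD
#' formula, enabling effect-size recomputation directly from published
#' tables.
#'
#' @param mean_a,mean_b Group means (control, case).
#' @param ci_a,ci_b Length-2 CI bounds for each group.
#' @param n_a,n_b Group sizes.
#' @return Cohen's d (positive when the case mean is higher).
#' @export
cohens_d_from_summary <- function(mean_a, ci_a, n_a, mean_b, ci_b, n_b) {
  sd_a <- reconstruct_sd_from_ci(mean_a, ci_a[1], ci_a[2], n_a)
  sd_b <- reconstruct_sd_from_ci(mean_b, ci_b[1], ci_b[2], n_b)
  sp <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
  if (sp == 0) stop("pooled standard deviation is zero")
  (mean_b - mean_a) / sp
}

#' Welch two-sample t statistic from summary statistics
#'
#' @param mean_a,sd_a,n_a First-group summaries.
#' @param mean_b,sd_b,n_b Second-group summaries.
#' @return List with `t` and Welch-Satterthwaite `df`.
#' @export
welch_t_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  se2a <- sd_a^2 / n_a; se2b <- sd_b^2 / n_b
  t <- (mean_a - mean_b) / sqrt(se2a + se2b)
  df <- (se2a + se2b)^2 / (se2a^2 / (n_a - 1) + se2b^2 / (n_b - 1))
  list(t = t, df = df)
}

roc_direction_levels <- function(labels) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("labels must contain exactly two classes")
  lv <- levels(labels)
  # positive class: "ADHD" if present, otherwise the second level
  pos <- if ("ADHD" %in% lv) "ADHD" else lv[2]
  c(setdiff(lv, pos), pos)
}

#' Trapezoidal ROC-AUC with DeLong confidence interval
#'
#' Empirical (trapezoidal) area under the ROC curve with midrank tie
#' handling -- equivalently `U / (n1 * n2)` -- and a DeLong
#' placement-value CI (via \pkg{pROC}).  Scores are oriented so that
#' higher values indicate the case (ADHD) class; areas below 0.5 are
#' reported as-is, never flipped, preserving directional claims.
#'
#' @param scores Numeric scores.
#' @param labels Two-class labels; the `ADHD` level (or the second factor
#'   level) is the positive class.
#' @param conf Confidence level.
#' @return List of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `positive_class`, `roc` (the underlying \pkg{pROC} object).
#' @export
roc_auc <- function(scores, labels, conf = 0.95) {
  lv <- roc_direction_levels(labels)
  r <- pROC::roc(response = factor(labels, levels = lv), predictor = scores,
                 levels = lv, direction = "<", quiet = TRUE)
  ci <- suppressWarnings(pROC::ci.auc(r, conf.level = conf, method = "delong"))
  structure(list(auc = as.numeric(pROC::auc(r)),
                 ci_low = max(0, ci[1]), ci_high = min(1, ci[3]),
                 positive_class = lv[2], roc = r),
            class = "roc_result")
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two scores measured on the same subjects using
#' the DeLong placement-value covariance estimate (via
#' \code{pROC::roc.test}); reports the z statistic, two-sided p, the AUC
#' difference and the estimated variance of that difference.
#'
#' @param scores_1,scores_2 Two score vectors over the same subjects.
#' @param labels Two-class labels.
#' @return List of class `delong_comparison`: `z`, `p`, `auc_difference`
#'   (`auc1 - auc2`), `var_diff`, `degenerate` flag.
#' @export
delong_test <- function(scores_1, scores_2, labels) {
  if (length(scores_1) != length(scores_2) ||
      length(scores_1) != length(labels))
    stop("scores and labels must align subject-for-subject")
  lv <- roc_direction_levels(labels)
  resp <- factor(labels, levels = lv)
  r1 <- pROC::roc(resp, scores_1, levels = lv, direction = "<", quiet = TRUE)
  r2 <- pROC::roc(resp, scores_2, levels = lv, direction = "<", quiet = TRUE)
  diff <- as.numeric(pROC::auc(r1)) - as.numeric(pROC::auc(r2))
  if (isTRUE(all.equal(scores_1, scores_2))) {
    return(structure(list(z = 0, p = 1, auc_difference = 0,
                          var_diff = NA_real_, degenerate = TRUE),
                     class = "delong_comparison"))
  }
  tst <- suppressWarnings(pROC::roc.test(r1, r2, method = "delong",
                                         paired = TRUE))
  z <- as.numeric(tst$statistic)
  degenerate <- !is.finite(z)
  if (degenerate && diff == 0) { z <- 0 }
  p <- if (is.finite(z)) 2 * pnorm(-abs(z)) else NA_real_
  var_diff <- if (is.finite(z) && z != 0) (diff / z)^2 else NA_real_
  structure(list(z = z, p = max(p, .Machine$double.xmin),
                 auc_difference = diff, var_diff = var_diff,
                 degenerate = degenerate),
            class = "delong_comparison")
}

#' Binormal AUC implied by an effect size
#'
#' For two equal-variance normal score distributions separated by `d`
#' pooled SDs, the ROC area is `pnorm(d / sqrt(2))` -- the closed-form
#' link between effect-size and ROC columns of a summary table.
#'
#' @param d Cohen's d.
#' @return AUC in `[0, 1]`.
#' @export
binormal_auc <- function(d) pnorm(d / sqrt(2))

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y Numeric vectors (n >= 4, non-degenerate).
#' @param conf Confidence level.
#' @return List: `r`, `ci_low`, `ci_high`, `n`, `p`.
#' @export
correlation_ci <- function(x, y, conf = 0.95) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input")
  ct <- cor.test(x, y, conf.level = conf)
  list(r = unname(ct$estimate), ci_low = ct$conf.int[1],
       ci_high = ct$conf.int[2], n = length(x), p = ct$p.value)
}

#' Fisher-z correlation CI from summary r and n
#'
#' @param r Pearson correlation.
#' @param n Sample size.
#' @param conf Confidence level.
#' @return Length-2 CI.
#' @export
correlation_ci_from_summary <- function(r, n, conf = 0.95) {
  z <- atanh(r); se <- 1 / sqrt(n - 3)
  q <- qnorm(1 - (1 - conf) / 2)
  tanh(c(z - q * se, z + q * se))
}
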