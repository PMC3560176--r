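#' Cohen's kappa for predicted versus actual class
#'
#' Chance-corrected agreement: `(p_o - p_e) / (1 - p_e)` with the chance
#' agreement `p_e` from the marginal products.
#'
#' @param predicted,actual Equal-length class vectors.
#' @return Kappa in `[-1, 1]`; `NA` (flagged by attribute) when chance
#'   agreement is 1.
#' @export
cohen_kappa <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("length mismatch")
  lv <- union(unique(as.character(predicted)), unique(as.character(actual)))
  p <- factor(as.character(predicted), levels = lv)
  a <- factor(as.character(actual), levels = lv)
  tab <- table(p, a) / length(p)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (isTRUE(all.equal(pe, 1))) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  (po - pe) / (1 - pe)
}

# rank-based AUC, P(score_case > score_control) + half ties;
# equals the exhaustive pair-counting value exactly
auc_rank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' The six model families of the predictive-modeling harness
#'
#' @return Character vector of family names accepted by [cv_compare()].
#' @export
cv_model_families <- function() {
  c("linear_discriminant", "general_linear", "multinomial_logistic",
    "neural_network", "support_vector", "random_forest")
}

# fit one family on the training rows and score the test rows;
# returns list(prob = case probability/score, class = predicted label)
fit_and_score <- function(family, x_train, y_train, x_test, control) {
  switch(family,
    linear_discriminant = {
      fit <- MASS::lda(x_train, grouping = y_train)
      pr <- predict(fit, x_test)
      list(prob = pr$posterior[, "ADHD"], class = as.character(pr$class))
    },
    general_linear = {
      # ordinary least-squares scoring of the 0/1 outcome
      df <- data.frame(y = as.integer(y_train == "ADHD"), x_train)
      fit <- lm(y ~ ., df)
      p <- predict(fit, data.frame(x_test))
      list(prob = p, class = ifelse(p >= 0.5, "ADHD", "control"))
    },
    multinomial_logistic = {
      df <- data.frame(y = as.integer(y_train == "ADHD"), x_train)
      fit <- suppressWarnings(glm(y ~ ., df, family = binomial()))
      p <- suppressWarnings(predict(fit, data.frame(x_test), type = "response"))
      list(prob = p, class = ifelse(p >= 0.5, "ADHD", "control"))
    },
    neural_network = {
      xs <- scale(x_train)
      ctr <- attr(xs, "scaled:center"); scl <- attr(xs, "scaled:scale")
      scl[scl == 0] <- 1
      fit <- nnet::nnet(xs, as.integer(y_train == "ADHD"),
                        size = control$nnet_size, decay = control$nnet_decay,
                        maxit = control$nnet_maxit, trace = FALSE)
      p <- as.numeric(predict(fit, scale(x_test, ctr, scl)))
      list(prob = p, class = ifelse(p >= 0.5, "ADHD", "control"))
    },
    support_vector = {
      fit <- e1071::svm(x_train, y_train, kernel = "radial",
                        cost = control$svm_cost, scale = TRUE)
      pr <- predict(fit, x_test, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      dec <- dv[, 1]
      # decision values are positive for the class named first; orient
      # so ADHD scores high
      if (startsWith(colnames(dv)[1], "control")) dec <- -dec
      list(prob = dec, class = as.character(pr))
    },
    random_forest = {
      fit <- randomForest::randomForest(x_train, y_train,
                                        ntree = control$rf_trees)
      p <- predict(fit, x_test, type = "prob")[, "ADHD"]
      list(prob = p, class = ifelse(p >= 0.5, "ADHD", "control"))
    },
    stop("unknown model family: ", family))
}

#' Repeated split-sample comparison of feature sets and model families
#'
#' The predictive-modeling harness: for each random stratified 75/25
#' split, each model family is trained on the 75% and scored on the held
#' -out 25%; accuracy, kappa, ROC-AUC, sensitivity and specificity
#' (ADHD as the positive class, 0.5 posterior threshold) are averaged
#' over splits.  The predictor matrix is age + sex + the 12 measures of
#' the chosen feature set.  Splits are generated once from the seed, so
#' different feature sets and families see identical partitions and can
#' be compared pairwise split-for-split.
#'
#' @param cohort Cohort data frame with `group`, `age`, `sex` and the
#'   feature columns.
#' @param feature_sets Subset of `"no4s_attention"`, `"cptii_attention"`,
#'   `"activity"`.
#' @param model_families Subset of [cv_model_families()].
#' @param n_splits Number of random splits (default 200).
#' @param split_fraction Training fraction (default 0.75).
#' @param seed Integer seed; (seed, n_splits) fully determines every
#'   partition.
#' @param rf_n_splits Optional larger split count used for the random
#'   forest family only (the harness default keeps it equal to
#'   `n_splits`).
#' @param control Hyperparameters: `nnet_size`, `nnet_decay`,
#'   `nnet_maxit`, `svm_cost`, `rf_trees`.
#' @return List of class `cv_comparison`: `summary` (one row per family
#'   x feature set with the five averaged criteria), `per_split` (split
#'   -level metric records), `n_splits`, `split_fraction`.
#' @export
cv_compare <- function(cohort,
                       feature_sets = c("no4s_attention", "cptii_attention",
                                        "activity"),
                       model_families = cv_model_families(),
                       n_splits = 200, split_fraction = 0.75, seed = 1,
                       rf_n_splits = n_splits,
                       control = list(nnet_size = 5, nnet_decay = 0.1,
                                      nnet_maxit = 150, svm_cost = 1,
                                      rf_trees = 300)) {
  feature_sets <- match.arg(feature_sets, several.ok = TRUE)
  model_families <- match.arg(model_families, cv_model_families(),
                              several.ok = TRUE)
  y <- factor(cohort$group, levels = c("control", "ADHD"))
  if (nlevels(droplevels(y)) < 2) stop("cohort must contain both groups")
  max_splits <- max(n_splits, rf_n_splits)
  idx_adhd <- which(y == "ADHD"); idx_ctrl <- which(y == "control")
  n_tr_a <- round(length(idx_adhd) * split_fraction)
  n_tr_c <- round(length(idx_ctrl) * split_fraction)
  set.seed(seed)
  splits <- lapply(seq_len(max_splits), function(i)
    c(sample(idx_adhd, n_tr_a), sample(idx_ctrl, n_tr_c)))
  xmats <- lapply(feature_sets, function(fs) {
    cols <- feature_block(fs)
    missing_cols <- setdiff(cols, names(cohort))
    if (length(missing_cols))
      stop("cohort lacks features: ", paste(missing_cols, collapse = ", "))
    as.matrix(data.frame(age = cohort$age,
                         sex = as.integer(cohort$sex == "male"),
                         cohort[, cols]))
  })
  names(xmats) <- feature_sets
  records <- list(); ri <- 1L
  for (fam in model_families) {
    fam_splits <- if (fam == "random_forest") rf_n_splits else n_splits
    for (fs in feature_sets) {
      x <- xmats[[fs]]
      for (si in seq_len(fam_splits)) {
        tr <- splits[[si]]
        te <- setdiff(seq_along(y), tr)
        res <- fit_and_score(fam, x[tr, , drop = FALSE], y[tr],
                             x[te, , drop = FALSE], control)
        truth <- y[te]
        pos <- truth == "ADHD"
        cls <- res$class
        acc <- mean(cls == as.character(truth))
        records[[ri]] <- data.frame(
          model_family = fam, feature_set = fs, split = si,
          accuracy = acc,
          kappa = cohen_kappa(cls, as.character(truth)),
          roc_auc = auc_rank(res$prob, pos),
          sensitivity = mean(cls[pos] == "ADHD"),
          specificity = mean(cls[!pos] == "control"))
        ri <- ri + 1L
      }
    }
  }
  per_split <- do.call(rbind, records)
  agg <- stats::aggregate(
    per_split[, c("accuracy", "kappa", "roc_auc", "sensitivity",
                  "specificity")],
    by = per_split[, c("model_family", "feature_set")], FUN = mean,
    na.rm = TRUE)
  structure(list(summary = agg, per_split = per_split,
                 n_splits = n_splits, split_fraction = split_fraction,
                 seed = seed),
            class = "cv_comparison")
}

#' Paired comparison of two feature sets over identical splits
#'
#' Tests whether one feature set outperforms another using the
#' split-level metric values over the same partitions: a paired t test
#' by default, falling back to a Wilcoxon signed-rank test when the
#' paired differences are clearly non-normal (Shapiro-Wilk p < 0.01).
#' Two-sided.
#'
#' @param metrics_a,metrics_b Per-split metric vectors from the same
#'   splits (e.g. filtered from a [cv_compare()] `per_split` table).
#' @param split_ids_a,split_ids_b Optional split identifiers; when
#'   supplied they must match exactly.
#' @return List: `p`, `statistic`, `method`, `mean_difference`
#'   (`a - b`).
#' @export
paired_feature_set_test <- function(metrics_a, metrics_b,
                                    split_ids_a = NULL, split_ids_b = NULL) {
  if (!is.null(split_ids_a) || !is.null(split_ids_b)) {
    if (!identical(split_ids_a, split_ids_b)) stop("mismatched split ids")
  }
  if (length(metrics_a) != length(metrics_b)) stop("mismatched split counts")
  d <- metrics_a - metrics_b
  if (all(d == 0))
    return(list(p = 1, statistic = 0, method = "paired t",
                mean_difference = 0))
  use_wilcox <- FALSE
  if (length(d) >= 4 && length(unique(d)) > 1 && sd(d) > 0) {
    sw <- tryCatch(shapiro.test(d[seq_len(min(length(d), 5000))]),
                   error = function(e) NULL)
    if (!is.null(sw) && sw$p.value < 0.01) use_wilcox <- TRUE
  }
  if (use_wilcox) {
    w <- suppressWarnings(wilcox.test(metrics_a, metrics_b, paired = TRUE))
    list(p = w$p.value, statistic = unname(w$statistic),
         method = "wilcoxon signed-rank", mean_difference = mean(d))
  } else {
    tt <- t.test(metrics_a, metrics_b, paired = TRUE)
    list(p = tt$p.value, statistic = unname(tt$statistic),
         method = "paired t", mean_difference = mean(d))
  }
}
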