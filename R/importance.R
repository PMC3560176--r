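#' Random-forest variable importance
#'
#' Grows a classification forest (default 10,000 trees, 4 variables
#' tried per split) and reports both importance criteria: the mean
#' decrease in out-of-bag accuracy when a variable is permuted, and the
#' mean decrease in Gini node impurity, together with the rank of each
#' variable under each criterion (rank 1 = most important).
#'
#' @param features Data frame / matrix of predictors.
#' @param labels Two-class (or multi-class) outcome.
#' @param n_trees Number of trees (default 10000).
#' @param m_try Variables tried per split (default 4).
#' @param seed Integer seed (forest growth is stochastic).
#' @return Data frame of class `importance_result`: `variable`,
#'   `mean_decrease_accuracy`, `mean_decrease_gini`, `rank_accuracy`,
#'   `rank_gini`, `constant` flag.
#' @export
rf_importance <- function(features, labels, n_trees = 10000, m_try = 4,
                          seed = 1) {
  features <- as.data.frame(features)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least two classes")
  if (ncol(features) < m_try)
    stop("fewer predictors than variables tried per split")
  constant <- vapply(features, function(v) length(unique(v)) == 1, logical(1))
  set.seed(seed)
  fit <- randomForest::randomForest(x = features, y = labels,
                                    ntree = n_trees, mtry = m_try,
                                    importance = TRUE)
  imp <- randomForest::importance(fit)
  acc <- imp[, "MeanDecreaseAccuracy"]
  gini <- imp[, "MeanDecreaseGini"]
  out <- data.frame(
    variable = colnames(features),
    mean_decrease_accuracy = as.numeric(acc),
    mean_decrease_gini = as.numeric(gini),
    rank_accuracy = rank(-acc, ties.method = "first"),
    rank_gini = rank(-gini, ties.method = "first"),
    constant = constant
  )
  if (any(constant))
    attr(out, "constant_flagged") <- out$variable[constant]
  class(out) <- c("importance_result", "data.frame")
  out
}

#' Agreement between two importance profiles
#'
#' Pearson correlation between two importance vectors over the same
#' variables -- used to compare the permutation-accuracy and
#' Gini-decrease criteria, or two independently seeded forests.
#'
#' @param result_a,result_b `importance_result` frames (or numeric
#'   vectors) over the same variable set.
#' @param criterion Which column to correlate when results are frames.
#' @return Pearson correlation.
#' @export
importance_agreement <- function(result_a, result_b,
                                 criterion = "mean_decrease_accuracy") {
  vec <- function(r) {
    if (is.data.frame(r)) {
      stopifnot(criterion %in% names(r))
      setNames(r[[criterion]], r$variable)
    } else r
  }
  a <- vec(result_a); b <- vec(result_b)
  if (length(a) != length(b)) stop("importance vectors differ in length")
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) stop("variable sets differ")
    b <- b[names(a)]
  }
  cor(as.numeric(a), as.numeric(b))
}
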