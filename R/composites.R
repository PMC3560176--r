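# Shared machinery for the weighted composite indices.  Features are
# standardized against control reference statistics, then weights come
# from a logistic regression of group on the standardized block.  The
# default fit is ridge-penalized (fixed moderate penalty): the composite
# instruments are meant to be stable population-fit scoring rules over
# 12+ strongly correlated measures, and an unpenalized fit on a finite
# calibration cohort chases sample-specific contrasts (and separates
# outright for the wide combined block).  `method = "ml"` gives the
# unpenalized fit, which still falls back to ridge on separation or
# non-convergence, flagged in the model.
fit_logistic_composite <- function(cohort, feature_names, label = "composite",
                                   ridge_lambda = 0.25,
                                   method = c("ridge", "ml")) {
  method <- match.arg(method)
  stopifnot(all(feature_names %in% names(cohort)))
  if (length(unique(cohort$group)) < 2)
    stop("calibration cohort must contain both groups")
  ctrl <- cohort[cohort$group == "control", feature_names, drop = FALSE]
  ref_mean <- vapply(ctrl, mean, numeric(1))
  ref_sd <- vapply(ctrl, sd, numeric(1))
  ref_sd[ref_sd == 0] <- 1
  x <- scale(as.matrix(cohort[, feature_names]), ref_mean, ref_sd)
  y <- as.integer(cohort$group == "ADHD")
  regularized <- method == "ridge"
  coefs <- NULL
  if (method == "ml") {
    sep <- FALSE
    fit <- withCallingHandlers(
      glm(y ~ x, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    coefs <- coef(fit)
    if (sep || anyNA(coefs) || max(abs(coefs[-1])) > 15) {
      regularized <- TRUE
      coefs <- NULL
    }
  }
  if (is.null(coefs)) {
    rfit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                           lambda = ridge_lambda, standardize = FALSE)
    coefs <- as.numeric(coef(rfit))
  }
  names(coefs) <- c("(Intercept)", feature_names)
  structure(list(label = label, feature_names = feature_names,
                 intercept = unname(coefs[1]),
                 weights = coefs[-1],
                 ref_mean = ref_mean, ref_sd = ref_sd,
                 regularized = regularized),
            class = "composite_model")
}

apply_logistic_composite <- function(model, features) {
  stopifnot(inherits(model, "composite_model"))
  if (is.data.frame(features))
    features <- as.matrix(features[, model$feature_names, drop = FALSE])
  x <- scale(features, model$ref_mean, model$ref_sd)
  as.numeric(model$intercept + x %*% model$weights)
}

#' Fit and apply the activity severity composite
#'
#' A treatment-responsive summary of hyperactivity: the 12 head and shin
#' movement measures are standardized against control reference
#' statistics and combined with logistic-regression weights fit on a
#' calibration cohort; the score is the linear predictor, oriented so
#' higher values are more ADHD-like.
#'
#' @param cohort Calibration cohort containing both groups and the 12
#'   movement measures.
#' @param ridge_lambda Ridge penalty of the instrument fit (fixed
#'   moderate default; see [fit_discriminative_index()] for why the
#'   instruments are penalized).
#' @return `fit_activity_composite` returns a `composite_model`;
#'   `apply_activity_composite` returns a numeric score per row.
#' @export
fit_activity_composite <- function(cohort, ridge_lambda = 0.25) {
  fit_logistic_composite(cohort, feature_block("activity"),
                         label = "activity_severity", ridge_lambda)
}

#' @rdname fit_activity_composite
#' @param model A fitted `composite_model`.
#' @param features Data frame (or matrix) with the model's feature
#'   columns.
#' @export
apply_activity_composite <- function(model, features) {
  apply_logistic_composite(model, features)
}

#' Fit and apply the distraction severity composite
#'
#' The attention-side analogue of the activity composite: a standardized
#' weighted sum over the 12 cognitive-control-task attention measures,
#' with logistic weights fit on a calibration cohort; higher = more
#' distracted.
#'
#' @inheritParams fit_activity_composite
#' @return A `composite_model` / numeric scores.
#' @export
fit_distraction_composite <- function(cohort, ridge_lambda = 0.25) {
  fit_logistic_composite(cohort, feature_block("no4s_attention"),
                         label = "distraction_severity", ridge_lambda)
}

#' @rdname fit_distraction_composite
#' @param model A fitted `composite_model`.
#' @param features Data frame with the model's feature columns.
#' @export
apply_distraction_composite <- function(model, features) {
  if (!inherits(model, "composite_model")) stop("unfitted composite model")
  apply_logistic_composite(model, features)
}

#' Fit and apply the combined discriminative index
#'
#' Logistic regression on the combined activity + attention feature block
#' (24 measures), the diagnostic index that unites both domains.  All
#' composite instruments use a ridge-penalized logistic fit with a fixed
#' moderate penalty: they are meant to be stable population-level scoring
#' rules, an unpenalized fit on a wide block of correlated measures
#' chases sample-specific contrasts, and for this 24-measure block a
#' maximum-likelihood fit separates outright on study-sized calibration
#' cohorts.  The discriminative index uses a lighter penalty than the
#' single-domain composites: it is the one instrument described as
#' explicitly optimized for case-control discrimination.
#'
#' @inheritParams fit_activity_composite
#' @return A `composite_model` / numeric scores.
#' @export
fit_discriminative_index <- function(cohort, ridge_lambda = 0.1) {
  fit_logistic_composite(
    cohort, c(feature_block("activity"), feature_block("no4s_attention")),
    label = "discriminative_index", ridge_lambda)
}

#' @rdname fit_discriminative_index
#' @param model A fitted `composite_model`.
#' @param features Data frame with the model's feature columns.
#' @export
apply_discriminative_index <- function(model, features) {
  apply_logistic_composite(model, features)
}

#' Fit and apply the letter-CPT confidence index
#'
#' Two-class linear discriminant on the five published predictor slots
#' (percent omissions, sex, age, response bias beta, RT-by-ISI slope);
#' the index is the posterior probability of the ADHD class scaled to
#' 0-100, read as the likelihood that the individual has a genuine
#' attention problem.
#'
#' @param cohort Calibration cohort with both groups and columns
#'   `cpt_eom`, `cpt_beta`, `cpt_rt_slope_isi`, `age`, `sex`.
#' @param n_targets Target-trial count used to convert omissions to
#'   percent omissions (default 324, i.e. 360 trials at 90% targets).
#' @return `fit_confidence_index` returns a `confidence_index_model`;
#'   `apply_confidence_index` returns an index in `[0, 100]` per row.
#' @export
fit_confidence_index <- function(cohort, n_targets = 324) {
  if (length(unique(cohort$group)) < 2)
    stop("calibration cohort must contain both groups")
  x <- confidence_predictors(cohort, n_targets)
  fit <- MASS::lda(x, grouping = factor(cohort$group,
                                        levels = c("control", "ADHD")))
  structure(list(lda = fit, n_targets = n_targets,
                 feature_names = colnames(x)),
            class = "confidence_index_model")
}

confidence_predictors <- function(cohort, n_targets) {
  cbind(pct_omissions = 100 * cohort$cpt_eom / n_targets,
        sex = as.integer(cohort$sex == "male"),
        age = cohort$age,
        beta = cohort$cpt_beta,
        rt_isi_slope = cohort$cpt_rt_slope_isi)
}

#' @rdname fit_confidence_index
#' @param model A fitted `confidence_index_model`.
#' @param cohort Data frame with the predictor columns.
#' @export
apply_confidence_index <- function(model, cohort) {
  stopifnot(inherits(model, "confidence_index_model"))
  x <- confidence_predictors(cohort, model$n_targets)
  100 * predict(model$lda, x)$posterior[, "ADHD"]
}

#' Serialize a composite model to JSON
#'
#' Persists composite weights and reference statistics (plus a content
#' hash of the configuration) so a fitted instrument can be reloaded and
#' applied elsewhere.
#'
#' @param model A `composite_model`.
#' @param path Output path (`.json`).
#' @return `read_composite_json` returns the reconstructed model.
#' @export
write_composite_json <- function(model, path) {
  stopifnot(inherits(model, "composite_model"))
  payload <- list(label = model$label, feature_names = model$feature_names,
                  intercept = model$intercept,
                  weights = as.list(model$weights),
                  ref_mean = as.list(model$ref_mean),
                  ref_sd = as.list(model$ref_sd),
                  regularized = model$regularized)
  payload$config_hash <- sprintf("h%08x", sum(utf8ToInt(paste(
    format(c(model$intercept, model$weights), digits = 10), collapse = ","))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_composite_json
#' @export
read_composite_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(label = p$label, feature_names = p$feature_names,
                 intercept = p$intercept,
                 weights = setNames(unlist(p$weights), p$feature_names),
                 ref_mean = setNames(unlist(p$ref_mean), p$feature_names),
                 ref_sd = setNames(unlist(p$ref_sd), p$feature_names),
                 regularized = isTRUE(p$regularized)),
            class = "composite_model")
}
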