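#' Study configuration
#'
#' Bundles every knob of the synthetic study reproduction: a master seed
#' (fanned out deterministically to per-stage child seeds), cohort and
#' calibration sizes, predictive-modeling split counts, forest sizes,
#' bootstrap resamples and the signal-level exemplar settings.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param n_adhd,n_control Analysis cohort sizes (study defaults 40/60).
#' @param n_calibration Per-group size of the separate calibration cohort
#'   on which composite instruments are fit.
#' @param cv_splits Repeated-split count for the five non-forest model
#'   families.
#' @param rf_cv_splits Split count for the random-forest family.
#' @param rf_cv_trees Trees per forest inside the split harness.
#' @param importance_trees Trees for the variable-importance forest.
#' @param importance_mtry Variables tried per split.
#' @param n_boot Bootstrap resamples for effect-size CIs.
#' @param simulate_signals Whether to run the signal-level exemplar path
#'   (trajectory + task simulation through the extractors).
#' @param exemplar_duration Exemplar session length, seconds.
#' @return A list of class `study_config`, with a `config_hash` field.
#' @export
study_config <- function(seed = 1, n_adhd = 40, n_control = 60,
                         n_calibration = 150, cv_splits = 200,
                         rf_cv_splits = 500, rf_cv_trees = 300,
                         importance_trees = 10000, importance_mtry = 4,
                         n_boot = 1000, simulate_signals = TRUE,
                         exemplar_duration = 300) {
  cfg <- list(seed = as.integer(seed), n_adhd = n_adhd,
              n_control = n_control, n_calibration = n_calibration,
              cv_splits = cv_splits, rf_cv_splits = rf_cv_splits,
              rf_cv_trees = rf_cv_trees,
              importance_trees = importance_trees,
              importance_mtry = importance_mtry, n_boot = n_boot,
              simulate_signals = simulate_signals,
              exemplar_duration = exemplar_duration)
  cfg$config_hash <- sprintf("h%08x", sum(utf8ToInt(paste(
    names(cfg), unlist(lapply(cfg, format)), collapse = "|"))))
  class(cfg) <- "study_config"
  cfg
}

# deterministic master-seed fanout; stage offsets keep modules independent
child_seed <- function(seed, k) as.integer((seed * 1009L + k) %% 2147483647L)

#' Per-measure group statistics table
#'
#' For every measure in a feature block: covariate-adjusted group means
#' with 95% CIs, the ANCOVA group F and p, a Benjamini-Hochberg q within
#' the block, Cohen's d with a bootstrap CI, and the trapezoidal ROC-AUC
#' with DeLong CI.  Mirrors the layout of a published per-measure summary
#' table.
#'
#' @param cohort Cohort data frame.
#' @param measures Character vector of measure columns.
#' @param n_boot Bootstrap resamples for the d CI.
#' @param seed Integer seed for the bootstrap.
#' @param directions Named +1/-1 vector giving each measure's
#'   hypothesized ADHD-high direction; ROC scores are oriented by it (so
#'   sample AUCs below 0.5 are reported as-is, never flipped post hoc).
#'   Defaults to the calibrated directions where known, else +1.
#' @return Data frame, one row per measure.
#' @export
measure_table <- function(cohort, measures, n_boot = 1000, seed = 1,
                          directions = NULL) {
  if (is.null(directions)) {
    gp <- group_parameters()
    directions <- setNames(rep(1, length(measures)), measures)
    known <- intersect(measures, gp$measure)
    directions[known] <- gp$direction[match(known, gp$measure)]
  }
  rows <- lapply(seq_along(measures), function(i) {
    m <- measures[i]
    adj <- ancova_adjust(cohort[[m]], cohort$group, cohort$age, cohort$sex)
    v <- adj$adjusted_values
    is_adhd <- cohort$group == "ADHD"
    ci <- function(x) mean(x) + c(-1, 1) * 1.96 * sd(x) / sqrt(length(x))
    es <- cohens_d(v[!is_adhd], v[is_adhd], n_boot = n_boot,
                   seed = child_seed(seed, i))
    roc <- roc_auc(v * directions[[m]], cohort$group)
    # d reported with the ADHD-high sign convention kept as-is
    data.frame(measure = m,
               control_mean = mean(v[!is_adhd]),
               control_lo = ci(v[!is_adhd])[1], control_hi = ci(v[!is_adhd])[2],
               adhd_mean = mean(v[is_adhd]),
               adhd_lo = ci(v[is_adhd])[1], adhd_hi = ci(v[is_adhd])[2],
               f_group = adj$f_group, p = adj$p,
               covariates = paste(adj$covariates_used, collapse = "+"),
               d = es$d, d_lo = es$ci_low, d_hi = es$ci_high,
               auc = roc$auc, auc_lo = roc$ci_low, auc_hi = roc$ci_high)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out
}

#' Run the full synthetic study
#'
#' End-to-end reproduction of the discriminability analysis on synthetic
#' data: sample a calibrated cohort, fit the composite instruments on a
#' separate calibration cohort, build the three per-measure summary
#' tables, the composite ROC comparison with pairwise DeLong tests, the
#' rating-correlation table, the random-forest importance profile and
#' the repeated split-sample model grid; optionally run the signal-level
#' exemplar path (simulated trajectories and task responses through the
#' feature extractors).  Deterministic under a fixed configuration.
#'
#' @param config A [study_config()].
#' @return A list of class `discriminability_report` with components
#'   `demographics`, `table1`, `table2`, `table3`, `figure2`, `figure3`,
#'   `table4`, `table5`, `paired_tests`, `exemplars`, `config`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  seed <- config$seed
  stage <- function(k) child_seed(seed, k)
  params <- group_parameters()

  # cohorts: analysis cohort at study scale, calibration cohort for the
  # composite instruments
  cohort <- sample_feature_cohort(params, config$n_adhd, config$n_control,
                                  seed = stage(1))
  calib <- sample_feature_cohort(params, config$n_calibration,
                                 config$n_calibration, seed = stage(2))

  # composite instruments (fit out-of-sample)
  act_model <- fit_activity_composite(calib)
  dis_model <- fit_distraction_composite(calib)
  idx_model <- fit_discriminative_index(calib)
  conf_model <- fit_confidence_index(calib)

  cohort$activity_composite <- apply_activity_composite(act_model, cohort)
  cohort$distraction_composite <- apply_distraction_composite(dis_model, cohort)
  cohort$discriminative_index <- apply_discriminative_index(idx_model, cohort)
  cohort$confidence_index <- apply_confidence_index(conf_model, cohort)

  # executive-function ratings reflect the activity composite at the
  # published correlation targets
  cohort <- sample_ratings(cohort, score = cohort$activity_composite,
                           target_correlation =
                             rating_correlation_table()$activity_composite,
                           seed = stage(3))

  is_adhd <- cohort$group == "ADHD"
  demographics <- list(
    n_adhd = sum(is_adhd), n_control = sum(!is_adhd),
    age = welch_t_from_summary(mean(cohort$age[!is_adhd]),
                               sd(cohort$age[!is_adhd]), sum(!is_adhd),
                               mean(cohort$age[is_adhd]),
                               sd(cohort$age[is_adhd]), sum(is_adhd)))

  table1 <- measure_table(cohort, feature_block("activity"),
                          n_boot = config$n_boot, seed = stage(4))
  table2 <- measure_table(cohort, feature_block("no4s_attention"),
                          n_boot = config$n_boot, seed = stage(5))
  table3 <- measure_table(cohort, feature_block("cptii_attention"),
                          n_boot = config$n_boot, seed = stage(6))

  composites <- c("activity_composite", "distraction_composite",
                  "confidence_index", "discriminative_index")
  rocs <- lapply(composites, function(cc) roc_auc(cohort[[cc]], cohort$group))
  names(rocs) <- composites
  pair_grid <- data.frame(
    a = c("activity_composite", "activity_composite",
          "discriminative_index", "discriminative_index"),
    b = c("distraction_composite", "confidence_index",
          "activity_composite", "distraction_composite"))
  delong <- lapply(seq_len(nrow(pair_grid)), function(i) {
    dl <- delong_test(cohort[[pair_grid$a[i]]], cohort[[pair_grid$b[i]]],
                      cohort$group)
    data.frame(score_a = pair_grid$a[i], score_b = pair_grid$b[i],
               auc_difference = dl$auc_difference, z = dl$z, p = dl$p)
  })
  figure2 <- list(
    auc = data.frame(composite = composites,
                     auc = vapply(rocs, function(r) r$auc, numeric(1)),
                     ci_low = vapply(rocs, function(r) r$ci_low, numeric(1)),
                     ci_high = vapply(rocs, function(r) r$ci_high, numeric(1))),
    delong = do.call(rbind, delong))

  # variable importance over all 36 measures
  imp_features <- cohort[, c(feature_block("activity"),
                             feature_block("no4s_attention"),
                             feature_block("cptii_attention"))]
  figure3 <- rf_importance(imp_features, cohort$group,
                           n_trees = config$importance_trees,
                           m_try = config$importance_mtry,
                           seed = stage(7))

  # rating correlations for all four composites
  ratings <- paste0("rating_", c("activation", "attention", "effort",
                                 "affective_control", "memory", "total"))
  table4 <- do.call(rbind, lapply(ratings, function(rt) {
    row <- data.frame(rating = sub("rating_", "", rt))
    for (cc in composites) {
      cr <- correlation_ci(cohort[[cc]], cohort[[rt]])
      row[[cc]] <- cr$r
      row[[paste0(cc, "_lo")]] <- cr$ci_low
      row[[paste0(cc, "_hi")]] <- cr$ci_high
    }
    row
  }))

  cv <- cv_compare(cohort, n_splits = config$cv_splits,
                   rf_n_splits = config$rf_cv_splits, seed = stage(8),
                   control = list(nnet_size = 5, nnet_decay = 0.1,
                                  nnet_maxit = 150, svm_cost = 1,
                                  rf_trees = config$rf_cv_trees))
  paired_tests <- do.call(rbind, lapply(cv_model_families(), function(fam) {
    ps <- cv$per_split[cv$per_split$model_family == fam, ]
    act <- ps[ps$feature_set == "activity", ]
    do.call(rbind, lapply(c("no4s_attention", "cptii_attention"), function(fs) {
      att <- ps[ps$feature_set == fs, ]
      k <- min(nrow(act), nrow(att))
      tt <- paired_feature_set_test(act$accuracy[seq_len(k)],
                                    att$accuracy[seq_len(k)],
                                    act$split[seq_len(k)],
                                    att$split[seq_len(k)])
      data.frame(model_family = fam, comparison = paste0("activity_vs_", fs),
                 mean_difference = tt$mean_difference, p = tt$p,
                 method = tt$method)
    }))
  }))

  exemplars <- NULL
  if (isTRUE(config$simulate_signals))
    exemplars <- run_signal_exemplars(config)

  report <- list(demographics = demographics,
                 cohort = cohort,
                 table1 = table1, table2 = table2, table3 = table3,
                 figure2 = figure2, figure3 = figure3,
                 table4 = table4, table5 = cv$summary,
                 cv = cv, paired_tests = paired_tests,
                 exemplars = exemplars,
                 models = list(activity = act_model, distraction = dis_model,
                               discriminative = idx_model,
                               confidence = conf_model),
                 config = config)
  class(report) <- "discriminability_report"
  report
}

# signal-level exemplar path: one sedate and one hyperactive subject are
# pushed through trajectory simulation, frame loss, feature extraction
# and both task simulators/scorers
run_signal_exemplars <- function(config) {
  seed <- config$seed
  dur <- config$exemplar_duration
  profiles <- list(
    control = movement_model_params(bout_rate = 4, bout_amplitude_scale = 6,
                                    path_roughness = 0.35,
                                    session_duration = dur),
    adhd = movement_model_params(bout_rate = 28, bout_amplitude_scale = 12,
                                 path_roughness = 0.6,
                                 session_duration = dur))
  out <- lapply(names(profiles), function(nm) {
    s <- child_seed(seed, if (nm == "control") 21 else 22)
    traj <- simulate_trajectory(profiles[[nm]], marker_id = "head", seed = s)
    traj <- inject_frame_loss(traj, 0.18, seed = s + 1L)
    feats <- motion_features(traj)
    stream <- simulate_no4s_stream(dur, seed = s + 2L)
    resp <- simulate_responses(stream, response_model_params(), seed = s + 3L)
    core <- score_no4s_core(resp$responses)
    cstream <- simulate_cptii_stream(seed = s + 4L)
    cresp <- simulate_responses(cstream, response_model_params(),
                                seed = s + 5L)
    cpt <- score_cptii(cresp$responses)
    list(profile = nm, motion = feats, no4s = core, cptii = cpt)
  })
  names(out) <- names(profiles)
  out
}

#' Check a report against the published qualitative and numeric targets
#'
#' Evaluates the reproduction checklist: the deterministic quantities
#' recomputable from the printed summary statistics (group age Welch t,
#' area fold-ratios, reconstructed effect sizes, effect-size fold ratios
#' between measurement domains, maximal explained rating variance) and
#' the qualitative orderings the study reports (composite ROC ordering,
#' importance block ordering, activity-model superiority in every model
#' family).
#'
#' @param report A [run_study()] report.
#' @return Data frame of class `paper_checklist`: `check`, `value`,
#'   `target`, `tolerance`, `pass`.
#' @export
validate_against_paper <- function(report) {
  needed <- c("table1", "table2", "table3", "figure2", "figure3", "table5")
  missing_parts <- needed[!vapply(needed, function(nm)
    !is.null(report[[nm]]), logical(1))]
  if (length(missing_parts)) {
    return(structure(data.frame(
      check = paste0("missing section: ", missing_parts),
      value = NA_real_, target = NA_real_, tolerance = NA_real_,
      pass = FALSE), class = c("paper_checklist", "data.frame")))
  }
  checks <- printed_summary_checks()
  # composite ROC ordering: combined > activity > both attention composites
  auc <- setNames(report$figure2$auc$auc, report$figure2$auc$composite)
  checks <- rbind(checks, data.frame(
    check = "composite ROC ordering (combined > activity > attention)",
    value = as.numeric(auc["discriminative_index"] > auc["activity_composite"] &
                         auc["activity_composite"] > auc["distraction_composite"] &
                         auc["activity_composite"] > auc["confidence_index"]),
    target = 1, tolerance = 0))
  # importance block ordering: shin > head > attention (mean importance)
  imp <- report$figure3
  block_mean <- function(cols) mean(imp$mean_decrease_accuracy[
    imp$variable %in% cols])
  shin <- block_mean(grep("^shin_", imp$variable, value = TRUE))
  head_m <- block_mean(grep("^head_", imp$variable, value = TRUE))
  attn <- block_mean(grep("^(no4s|cpt)_", imp$variable, value = TRUE))
  checks <- rbind(checks, data.frame(
    check = "importance ordering (shin > head > attention)",
    value = as.numeric(shin > head_m && head_m > attn),
    target = 1, tolerance = 0))
  # model grid: activity beats both attention sets in every family
  t5 <- report$table5
  fams <- unique(t5$model_family)
  superior <- vapply(fams, function(f) {
    acc <- setNames(t5$accuracy[t5$model_family == f],
                    t5$feature_set[t5$model_family == f])
    acc["activity"] > acc["no4s_attention"] &&
      acc["activity"] > acc["cptii_attention"]
  }, logical(1))
  checks <- rbind(checks, data.frame(
    check = "activity-model superiority in all families",
    value = as.numeric(all(superior)), target = 1, tolerance = 0))
  checks$pass <- abs(checks$value - checks$target) <= checks$tolerance
  class(checks) <- c("paper_checklist", "data.frame")
  checks
}

# deterministic checks recomputable from the printed tables alone
printed_summary_checks <- function() {
  dem <- study_demographics()
  tab <- calibration_table()
  wt <- welch_t_from_summary(dem$age_mean_control, dem$age_sd_control,
                             dem$n_control, dem$age_mean_adhd,
                             dem$age_sd_adhd, dem$n_adhd)
  row_of <- function(m) tab[tab$measure == m, ]
  d_shin_ts <- with(row_of("shin_temporal"), cohens_d_from_summary(
    control_mean, c(control_lo, control_hi), dem$n_control,
    adhd_mean, c(adhd_lo, adhd_hi), dem$n_adhd))
  # printed effect sizes are magnitudes (positive for ADHD deficits in
  # either direction), so the reconstruction compares |d|
  d_attentive <- abs(with(row_of("no4s_pct_attentive"), cohens_d_from_summary(
    control_mean, c(control_lo, control_hi), dem$n_control,
    adhd_mean, c(adhd_lo, adhd_hi), dem$n_adhd)))
  mean_d <- function(panel) mean(tab$d[tab$panel %in% panel])
  fold12 <- mean_d(c("head", "shin")) / mean_d("no4s")
  fold13 <- mean_d(c("head", "shin")) / mean_d("cptii")
  max_var <- 100 * max(rating_correlation_table()$discriminative_index)^2
  data.frame(
    check = c("group age Welch t", "head area fold-ratio",
              "shin area fold-ratio", "shin temporal scaling d",
              "percent-time-attentive d",
              "activity/no4s effect-size fold (nearest integer)",
              "activity/cptii effect-size fold (nearest integer)",
              "max explained rating variance (%)"),
    value = c(wt$t,
              row_of("head_area")$adhd_mean / row_of("head_area")$control_mean,
              row_of("shin_area")$adhd_mean / row_of("shin_area")$control_mean,
              d_shin_ts, d_attentive, round(fold12), round(fold13), max_var),
    target = c(-3.06, 2.2, 3.6, 1.6, 0.87, 2, 3, 52),
    tolerance = c(0.01, 0.05, 0.05, 0.05, 0.03, 0, 0, 1))
}

#' Write a report's tables to disk
#'
#' Emits the per-measure tables, composite ROC summary, importance
#' listing, rating correlations and model grid as CSV plus a JSON
#' digest; every file records the configuration hash.
#'
#' @param report A `discriminability_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    df$config_hash <- report$config$config_hash
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  emit(report$table1, "table1_movement")
  emit(report$table2, "table2_no4s")
  emit(report$table3, "table3_cptii")
  emit(report$figure2$auc, "figure2_composite_auc")
  emit(report$figure2$delong, "figure2_delong")
  emit(as.data.frame(report$figure3), "figure3_importance")
  emit(report$table4, "table4_rating_correlations")
  emit(report$table5, "table5_cv_grid")
  emit(report$paired_tests, "table5_paired_tests")
  digest <- list(config = unclass(report$config),
                 demographics = report$demographics,
                 composite_auc = report$figure2$auc)
  jpath <- file.path(dir, "report_digest.json")
  jsonlite::write_json(digest, jpath, auto_unbox = TRUE, digits = NA)
  invisible(c(files, jpath))
}
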