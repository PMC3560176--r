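#' Published group summary statistics used to calibrate the synthetic cohort
#'
#' The case-control study this package models reported, for 40 adults with
#' ADHD and 60 healthy controls, per-measure group means with 95%
#' confidence intervals for 12 movement measures (6 head + 6 shin), 12
#' cognitive-control-task attention measures and 12 letter-CPT measures,
#' together with ANCOVA group F values, Cohen's d effect sizes and
#' ROC areas.  These printed summaries are the calibration inputs for the
#' synthetic-cohort generator: subject-level data were never deposited, so
#' per-group standard deviations are reconstructed from the CI half-widths
#' via [reconstruct_sd_from_ci()].
#'
#' Columns: `measure` (machine key), `label` (printed row label), `panel`
#' (`head`, `shin`, `no4s`, `cptii`), `control_mean`, `control_lo`,
#' `control_hi`, `adhd_mean`, `adhd_lo`, `adhd_hi` (group means and 95% CI
#' bounds in measure units), `f_group` (printed ANCOVA group F), `d`
#' (printed Cohen's d), `auc` (printed ROC area), `family` (sampling
#' family, `"normal"` or `"lognormal"`), `block` (instrument block:
#' `motion`, `no4s`, `cptii`).
#'
#' @return A data frame with 36 rows, one per measure.
#' @seealso [group_parameters()], [sample_feature_cohort()]
#' @export
calibration_table <- function() {
  # printed group summaries: movement panel (head + shin)
  motion <- data.frame(
    measure = c("head_immobility", "head_microevents", "head_displacement",
                "head_area", "head_spatial", "head_temporal",
                "shin_immobility", "shin_microevents", "shin_displacement",
                "shin_area", "shin_spatial", "shin_temporal"),
    label = rep(c("Immobility duration (sec)", "Microevents",
                  "Displacement (m)", "Area (cm2)", "Spatial Complexity",
                  "Temporal Scaling"), 2),
    panel = rep(c("head", "shin"), each = 6),
    control_mean = c(0.42, 1283, 2.25, 65.02, 1.31, 0.41,
                     4.84, 250.7, 0.44, 12.65, 2.22, 0.07),
    control_lo = c(0.33, 1055, 1.62, 45.38, 1.25, 0.34,
                   3.60, 149.6, 0.21, 6.32, 2.02, -0.001),
    control_hi = c(0.50, 1511, 2.89, 84.66, 1.37, 0.49,
                   6.08, 351.8, 0.67, 18.99, 2.42, 0.14),
    adhd_mean = c(0.18, 2255, 3.94, 145.6, 1.11, 0.63,
                  0.74, 1048.4, 1.93, 45.36, 1.33, 0.49),
    adhd_lo = c(0.16, 1907, 3.28, 116.6, 1.09, 0.56,
                0.53, 680.4, 1.23, 32.79, 1.26, 0.42),
    adhd_hi = c(0.21, 2603, 4.59, 174.7, 1.13, 0.71,
                0.94, 1416.5, 2.64, 57.92, 1.40, 0.57),
    f_group = c(14.97, 19.36, 11.65, 24.09, 25.71, 12.58,
                29.62, 23.69, 22.42, 27.09, 44.44, 57.25),
    d = c(0.85, 1.00, 0.73, 0.98, 1.08, 0.83,
          1.10, 1.01, 0.96, 1.05, 1.45, 1.60),
    auc = c(0.77, 0.79, 0.79, 0.82, 0.85, 0.72,
            0.88, 0.88, 0.88, 0.88, 0.87, 0.88)
  )

  # cognitive control (No-4's style) attention panel
  no4s <- data.frame(
    measure = c("no4s_accuracy", "no4s_eom", "no4s_eoc", "no4s_latency",
                "no4s_latency_sd", "no4s_latency_cov", "no4s_shifts",
                "no4s_pct_attentive", "no4s_pct_distracted",
                "no4s_pct_impulsive", "no4s_pct_random", "no4s_pct_minimal"),
    label = c("Accuracy (%)", "Errors of Omission", "Errors of Commission",
              "Latency (msec)", "Latency SD", "Latency COV",
              "Attention Shift", "Attentive (% time)", "Distracted (% time)",
              "Impulsive (% time)", "Random (% time)", "Minimal (% time)"),
    panel = "no4s",
    control_mean = c(97.46, 0.54, 20.48, 482.9, 97.93, 20.37, 13.95,
                     60, 16, 23, 0.22, 0.19),
    control_lo = c(97.00, 0.33, 16.87, 467.1, 90.38, 19.06, 12.62,
                   55, 13, 19, 0.0, 0.0),
    control_hi = c(97.93, 0.76, 24.09, 498.7, 105.5, 21.67, 15.28,
                   65, 20, 27, 0.4, 0.5),
    adhd_mean = c(95.76, 1.5, 30.71, 481.6, 119.4, 24.32, 15.22,
                  42, 25, 32, 0.76, 0.99),
    adhd_lo = c(94.87, 0.86, 24.84, 459.5, 108.6, 22.58, 13.93,
                35, 19, 26, 0.1, 0.2),
    adhd_hi = c(96.65, 2.13, 36.58, 503.7, 130.1, 26.07, 16.52,
                49, 31, 39, 1.4, 1.8),
    f_group = c(16.83, 9.22, 11.23, 0.11, 8.75, 13.43, 2.27,
                19.28, 4.78, 7.41, 1.92, 4.09),
    d = c(0.76, 0.67, 0.64, 0.02, 0.69, 0.76, 0.27,
          0.87, 0.54, 0.51, 0.36, 0.44),
    auc = c(0.71, 0.71, 0.67, 0.52, 0.70, 0.73, 0.58,
            0.73, 0.65, 0.62, 0.54, 0.56)
  )

  # letter CPT panel
  cptii <- data.frame(
    measure = c("cpt_eom", "cpt_eoc", "cpt_rt", "cpt_rt_se",
                "cpt_rt_block_var", "cpt_dprime", "cpt_beta",
                "cpt_perseverations", "cpt_rt_slope_blocks",
                "cpt_rt_se_slope_blocks", "cpt_rt_slope_isi",
                "cpt_rt_se_slope_isi"),
    label = c("Errors of Omission", "Errors of Commission",
              "Correct Reaction Time (RT)", "RT Standard Error (RT SE)",
              "Variability in RT by Blocks", "Discriminability (d prime)",
              "Response Bias (beta)", "Perseverative errors",
              "Change in RT by Blocks", "Change in RT SE by Blocks",
              "Change in RT by ISI", "Change in RT SE by ISI"),
    panel = "cptii",
    control_mean = c(1.95, 8.70, 385.2, 5.31, 6.76, 0.96, 0.91, 0.19,
                     0, 0, 0.05, 0.01),
    control_lo = c(0.91, 7.26, 370.5, 4.86, 5.87, 0.84, 0.62, 0.03,
                   -0.007, -0.021, 0.035, -0.011),
    control_hi = c(2.98, 10.15, 399.9, 5.77, 7.65, 1.07, 1.20, 0.36,
                   0.007, 0.014, 0.063, 0.039),
    adhd_mean = c(1.79, 12.26, 389.3, 6.35, 8.65, 0.74, 0.68, 0.71,
                  0, 0, 0.07, 0.06),
    adhd_lo = c(0.93, 10.11, 369.8, 5.65, 7.14, 0.61, 0.45, 0.19,
                -0.012, -0.034, 0.056, 0.015),
    adhd_hi = c(2.65, 14.42, 408.9, 7.05, 10.16, 0.88, 0.92, 1.23,
                0.017, 0.023, 0.086, 0.095),
    f_group = c(0.15, 8.30, 0.01, 8.13, 7.55, 3.95, 1.45, 7.07,
                0.02, 0.02, 4.5, 4.41),
    d = c(0.05, 0.60, 0.07, 0.55, 0.48, 0.49, 0.23, 0.46,
          0.08, 0.02, 0.43, 0.39),
    auc = c(0.47, 0.67, 0.52, 0.63, 0.63, 0.66, 0.57, 0.61,
            0.51, 0.50, 0.61, 0.60)
  )

  tab <- rbind(motion, no4s, cptii)

  # Sampling family: lognormal for the strictly positive, visibly skewed
  # count/extent measures (microevents, displacement, area, commissions);
  # normal otherwise (several CIs touch or cross zero).
  lognormal <- c("head_microevents", "head_displacement", "head_area",
                 "shin_microevents", "shin_displacement", "shin_area",
                 "no4s_eoc", "cpt_eoc")
  tab$family <- ifelse(tab$measure %in% lognormal, "lognormal", "normal")

  # Instrument block: the motion system (head + shin markers, one
  # session) versus the two attention tasks.  Within-subject dependence
  # is generated per block (see group_parameters()).
  tab$block <- ifelse(tab$panel %in% c("head", "shin"), "motion", tab$panel)
  rownames(tab) <- NULL
  tab
}

#' Published cohort demographics
#'
#' Group sizes, sex composition and age summaries of the modeled study
#' sample: 40 adults with ADHD (23M/17F, age 35 +/- 10 years) and 60
#' healthy controls (28M/32F, age 29 +/- 9 years), ages 18-57, with 17
#' ADHD subjects (9M/8F) classified as predominantly inattentive.
#'
#' @return A list with components `n_adhd`, `n_control`, `adhd_males`,
#'   `control_males`, `age_mean_adhd`, `age_sd_adhd`, `age_mean_control`,
#'   `age_sd_control`, `age_range`, `n_inattentive`.
#' @export
study_demographics <- function() {
  list(n_adhd = 40L, n_control = 60L,
       adhd_males = 23L, control_males = 28L,
       age_mean_adhd = 35, age_sd_adhd = 10,
       age_mean_control = 29, age_sd_control = 9,
       age_range = c(18, 57), n_inattentive = 17L)
}

#' Published correlations between composite indices and executive-function ratings
#'
#' Pearson correlations between the four composite indices and the six
#' Brown ADD executive-function rating domains, as printed in the source
#' study (n = 89 subjects with complete ratings assumed for CI
#' reconstruction).
#'
#' @return A data frame with columns `rating`, `confidence_index`,
#'   `distraction_composite`, `activity_composite`, `discriminative_index`.
#' @export
rating_correlation_table <- function() {
  data.frame(
    rating = c("activation", "attention", "effort", "affective_control",
               "memory", "total"),
    confidence_index = c(0.25, 0.23, 0.33, 0.23, 0.28, 0.28),
    distraction_composite = c(0.23, 0.28, 0.28, 0.23, 0.26, 0.28),
    activity_composite = c(0.51, 0.54, 0.51, 0.40, 0.49, 0.54),
    discriminative_index = c(0.66, 0.72, 0.60, 0.52, 0.62, 0.68)
  )
}

#' Published cross-validated model accuracies
#'
#' Accuracy ranges of the published repeated split-sample models by
#' feature set, used only as qualitative reproduction targets.
#'
#' @return A list of length-2 numeric ranges.
#' @keywords internal
published_cv_accuracy_ranges <- function() {
  list(activity = c(0.766, 0.842),
       no4s_attention = c(0.650, 0.720),
       cptii_attention = c(0.624, 0.709))
}
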