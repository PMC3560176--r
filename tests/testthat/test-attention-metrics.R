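test_that("core task scoring matches the hand-scored worked log", {
  log <- worked_log()
  sc <- score_no4s_core(log)
  expect_equal(sc$accuracy, 80)
  expect_equal(sc$eom, 1)
  expect_equal(sc$eoc, 1)
  expect_equal(sc$latency, 440)
  expect_equal(sc$latency_cov, 100 * sc$latency_sd / sc$latency)
})

test_that("degenerate responders score as expected", {
  st <- simulate_no4s_stream(300, seed = 2)
  all_resp <- st; all_resp$responded <- TRUE; all_resp$rt_ms <- 400
  sc <- score_no4s_core(all_resp)
  expect_equal(sc$eom, 0)
  expect_equal(sc$eoc, sum(!st$is_target))
  none <- st; none$responded <- FALSE; none$rt_ms <- NA_real_
  sc0 <- score_no4s_core(none)
  expect_true(is.na(sc0$latency))
  expect_false(attr(sc0, "latency_defined"))
})

test_that("score conservation holds on simulated sessions", {
  st <- simulate_no4s_stream(600, seed = 3)
  rp <- simulate_responses(st, response_model_params(), seed = 4)
  sc <- score_no4s_core(rp$responses)
  hits <- sum(rp$responses$is_target & rp$responses$responded)
  cr <- sum(!rp$responses$is_target & !rp$responses$responded)
  expect_equal(sc$eom + hits, sum(st$is_target))
  expect_equal(sc$eoc + cr, sum(!st$is_target))
})

test_that("latency COV is invariant to uniform RT rescaling", {
  log <- worked_log()
  sc1 <- score_no4s_core(log)
  log$rt_ms <- log$rt_ms * 3.7
  sc2 <- score_no4s_core(log)
  expect_equal(sc1$latency_cov, sc2$latency_cov)
})

test_that("epoch features partition the session correctly", {
  st <- simulate_no4s_stream(1200, seed = 5)
  rp <- simulate_responses(st, response_model_params(), seed = 6)
  ef <- build_epoch_features(rp$responses, session_duration = 1200)
  expect_equal(nrow(ef), 40)
  # fixture: 10 trials all inside the first epoch of a 60-s session
  log <- worked_log()
  ef2 <- build_epoch_features(log, session_duration = 60)
  expect_equal(nrow(ef2), 2)
  expect_equal(ef2$hit_rate[1], 8 / 9)
  expect_equal(ef2$fa_rate[1], 1)
  expect_equal(ef2$n_responses[1], 9)
  expect_true(ef2$empty[2])
  expect_equal(ef2$hit_rate[2], 0)
})

test_that("the epoch classifier recovers well-separated states", {
  states <- attention_states()
  centroids <- matrix(c(
    0.95, 0.05, 450, 50, 10,
    0.70, 0.30, 600, 140, 9,
    0.95, 0.90, 300, 60, 12,
    0.50, 0.50, 500, 250, 7,
    0.05, 0.05, 700, 80, 1), nrow = 5, byrow = TRUE)
  sds <- c(0.04, 0.04, 20, 10, 0.5)  # centroid gaps >= 4 pooled sd
  gen <- function(n, seed) {
    set.seed(seed)
    lab <- sample(states, n, replace = TRUE)
    f <- t(vapply(lab, function(s) {
      i <- match(s, states)
      rnorm(5, centroids[i, ], sds)
    }, numeric(5)))
    colnames(f) <- c("hit_rate", "fa_rate", "rt_mean", "rt_sd", "n_responses")
    list(features = as.data.frame(f), labels = lab)
  }
  tr <- gen(400, 1); te <- gen(400, 2)
  clf <- fit_state_lda(tr$features, tr$labels)
  pred <- classify_epochs(clf, te$features)
  expect_gte(mean(as.character(pred$state) == te$labels), 0.95)
  # an epoch exactly at a centroid classifies to its own state
  cen <- as.data.frame(centroids)
  colnames(cen) <- c("hit_rate", "fa_rate", "rt_mean", "rt_sd", "n_responses")
  pc <- classify_epochs(clf, cen)
  expect_equal(as.character(pc$state), states)
  # permuted training labels collapse held-out accuracy to chance --
  # checked on overlapping classes, where no coincidental label-cluster
  # alignment can survive (with widely separated clusters even a
  # permutation's ~20% self-agreement re-aligns the discriminant)
  gen_overlap <- function(n, seed) {
    set.seed(seed)
    lab <- sample(states, n, replace = TRUE)
    f <- t(vapply(lab, function(s)
      rnorm(5, centroids[match(s, states), ], 20 * sds), numeric(5)))
    colnames(f) <- c("hit_rate", "fa_rate", "rt_mean", "rt_sd", "n_responses")
    list(features = as.data.frame(f), labels = lab)
  }
  tro <- gen_overlap(400, 5); teo <- gen_overlap(400, 6)
  set.seed(9)
  clf0 <- fit_state_lda(tro$features, sample(tro$labels))
  pred0 <- classify_epochs(clf0, teo$features)
  expect_lt(mean(as.character(pred0$state) == teo$labels), 0.30)
  expect_error(fit_state_lda(tr$features[tr$labels != "minimal", ],
                             tr$labels[tr$labels != "minimal"]), "minimal")
})

test_that("state summaries count time shares and shifts", {
  expect_equal(summarize_states(rep("attentive", 40))$attention_shifts, 0)
  expect_equal(summarize_states(rep("attentive", 40))$pct_attentive, 100)
  alt <- rep(c("attentive", "distracted"), 20)
  s <- summarize_states(alt)
  expect_equal(s$attention_shifts, 39)
  expect_equal(s$pct_attentive, 50)
  fix <- c(rep("attentive", 25), rep("impulsive", 5), rep("distracted", 8),
           "minimal", "random")
  sf <- summarize_states(fix)
  expect_equal(sf$pct_impulsive, 12.5)
  expect_equal(sf$attention_shifts, 4)
  expect_error(summarize_states(c("attentive", "bogus")), "unknown")
})

test_that("percent-time estimates track hidden occupancy across subjects", {
  params <- response_model_params()
  gen_sub <- function(seed) {
    st <- simulate_no4s_stream(1200, seed = seed)
    rp <- simulate_responses(st, params, seed = seed + 50000)
    f <- build_epoch_features(rp$responses, session_duration = 1200)
    f$label <- rp$states$state[f$epoch]
    f
  }
  train <- do.call(rbind, lapply(1:40, gen_sub))
  clf <- fit_state_lda(train, train$label)
  test <- do.call(rbind, lapply(41:240, gen_sub))
  pred <- classify_epochs(clf, test)
  est <- summarize_states(pred$state)
  hid <- summarize_states(test$label)
  for (s in attention_states())
    expect_lt(abs(est[[paste0("pct_", s)]] - hid[[paste0("pct_", s)]]), 5)
})

test_that("letter-CPT signal detection follows the clipped-rate formulas", {
  # symmetric random responder: d' ~ 0, beta ~ 1
  mk_resp <- function(hit, fa, n_t = 900, n_nt = 100, rt = 400) {
    st <- data.frame(task = "cptii", trial_index = seq_len(n_t + n_nt),
                     onset_ms = seq_len(n_t + n_nt) * 1000,
                     stimulus_code = "A",
                     is_target = rep(c(TRUE, FALSE), c(n_t, n_nt)),
                     block = rep(1:6, length.out = n_t + n_nt),
                     sub_block = rep(1:3, length.out = n_t + n_nt),
                     isi_ms = rep(c(1000, 2000, 4000), length.out = n_t + n_nt))
    st$responded <- ifelse(st$is_target, runif(n_t + n_nt) < hit,
                           runif(n_t + n_nt) < fa)
    st$rt_ms <- ifelse(st$responded, rt, NA)
    st
  }
  set.seed(13)
  rnd <- score_cptii(mk_resp(0.5, 0.5, 5000, 5000))
  expect_lt(abs(rnd$cpt_dprime), 0.1)
  expect_lt(abs(rnd$cpt_beta - 1), 0.1)
  # exact rates 0.9 / 0.1 at N = 100 each: d' = 2 * qnorm(0.9)
  st <- mk_resp(1, 0, 100, 100)
  st$responded <- c(rep(c(TRUE, FALSE), c(90, 10)), rep(c(TRUE, FALSE), c(10, 90)))
  st$rt_ms <- ifelse(st$responded, 400, NA)
  ex <- score_cptii(st)
  expect_equal(ex$cpt_dprime, 2 * qnorm(0.9), tolerance = 1e-6)
  expect_equal(ex$cpt_dprime, 2.563, tolerance = 1e-3)
})

test_that("d-prime increases in hit rate at fixed false-alarm rate", {
  clip <- function(r, n) pmin(pmax(r, 1 / (2 * n)), 1 - 1 / (2 * n))
  hits <- seq(0.5, 0.99, by = 0.07)
  ds <- qnorm(clip(hits, 100)) - qnorm(clip(0.1, 100))
  expect_true(all(diff(ds) > 0))
})

test_that("RT regression slopes and perseverations are scored exactly", {
  n <- 360
  st <- simulate_cptii_stream(seed = 21)
  st$responded <- st$is_target
  # RT increases exactly 10 ms per block
  st$rt_ms <- ifelse(st$responded, 300 + 10 * st$block, NA)
  sc <- score_cptii(st)
  expect_equal(sc$cpt_rt_slope_blocks, 10, tolerance = 1e-9)
  expect_equal(sc$cpt_perseverations, 0)
  st$rt_ms[which(st$responded)[1:7]] <- 80
  expect_equal(score_cptii(st)$cpt_perseverations, 7)
  # no responses: signal-detection block flagged undefined
  st0 <- st; st0$responded <- FALSE; st0$rt_ms <- NA
  sc0 <- score_cptii(st0)
  expect_false(attr(sc0, "sdt_defined"))
  expect_true(is.na(sc0$cpt_rt))
})

test_that("composite instruments orient toward the deficit direction", {
  params <- group_parameters()
  calib <- sample_feature_cohort(params, 150, 150, seed = 61)
  act <- fit_activity_composite(calib)
  # control reference input scores at the intercept
  ref <- as.data.frame(as.list(act$ref_mean))
  expect_equal(apply_activity_composite(act, ref), act$intercept)
  # raising shin microevents raises the score
  up <- ref; up$shin_microevents <- up$shin_microevents + 500
  expect_gt(apply_activity_composite(act, up),
            apply_activity_composite(act, ref))
  dis <- fit_distraction_composite(calib)
  refd <- as.data.frame(as.list(dis$ref_mean))
  upd <- refd; upd$no4s_eom <- upd$no4s_eom + 3
  expect_gt(apply_distraction_composite(dis, upd),
            apply_distraction_composite(dis, refd))
  expect_error(apply_distraction_composite(list(), refd), "unfitted")
  expect_error(fit_activity_composite(calib[calib$group == "ADHD", ]),
               "both groups")
})

test_that("activity composite discriminates at least as well as single measures", {
  params <- group_parameters()
  calib <- sample_feature_cohort(params, 150, 150, seed = 62)
  study <- sample_feature_cohort(params, 40, 60, seed = 63)
  act <- fit_activity_composite(calib)
  auc_comp <- roc_auc(apply_activity_composite(act, study), study$group)$auc
  singles <- vapply(feature_block("activity"), function(m) {
    dir <- group_parameters()$direction[match(m, group_parameters()$measure)]
    roc_auc(dir * study[[m]], study$group)$auc
  }, numeric(1))
  expect_gte(auc_comp, max(singles) - 0.02)
})

test_that("attention composites fall in their published discrimination bands", {
  params <- group_parameters()
  calib <- sample_feature_cohort(params, 150, 150, seed = 64)
  eval_cohort <- sample_feature_cohort(params, 1000, 1000, seed = 65)
  dis <- fit_distraction_composite(calib)
  auc_dis <- roc_auc(apply_distraction_composite(dis, eval_cohort),
                     eval_cohort$group)$auc
  expect_gt(auc_dis, 0.55)
  expect_lt(auc_dis, 0.80)
  conf <- fit_confidence_index(calib)
  idx <- apply_confidence_index(conf, eval_cohort)
  expect_true(all(idx >= 0 & idx <= 100))
  auc_conf <- roc_auc(idx, eval_cohort$group)$auc
  expect_gt(auc_conf, 0.55)
  expect_lt(auc_conf, 0.75)
})

test_that("composite models serialize to JSON and back", {
  params <- group_parameters()
  calib <- sample_feature_cohort(params, 100, 100, seed = 66)
  act <- fit_activity_composite(calib)
  path <- tempfile(fileext = ".json")
  write_composite_json(act, path)
  back <- read_composite_json(path)
  study <- sample_feature_cohort(params, 20, 20, seed = 67)
  expect_equal(apply_activity_composite(back, study),
               apply_activity_composite(act, study), tolerance = 1e-10)
})
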