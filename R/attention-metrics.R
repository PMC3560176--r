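#' Core scoring of the cognitive control task
#'
#' Computes overall accuracy, errors of omission (unanswered targets),
#' errors of commission (responses to non-targets) and correct-response
#' latency statistics.  Latency statistics are computed over correct
#' target responses only; the coefficient of variation is
#' `100 * sd / mean`.
#'
#' @param responses Response data frame (one row per trial with
#'   `is_target`, `responded`, `rt_ms`).
#' @return One-row data frame: `accuracy` (%), `eom`, `eoc`, `latency`
#'   (ms), `latency_sd` (ms), `latency_cov` (%).  With no correct
#'   responses the latency fields are `NA` and flagged via the
#'   `latency_defined` attribute.
#' @export
score_no4s_core <- function(responses) {
  stopifnot(all(c("is_target", "responded") %in% names(responses)))
  correct <- (responses$is_target & responses$responded) |
    (!responses$is_target & !responses$responded)
  eom <- sum(responses$is_target & !responses$responded)
  eoc <- sum(!responses$is_target & responses$responded)
  rts <- responses$rt_ms[responses$is_target & responses$responded]
  rts <- rts[!is.na(rts)]
  has_rt <- length(rts) >= 1
  out <- data.frame(
    accuracy = 100 * mean(correct),
    eom = eom, eoc = eoc,
    latency = if (has_rt) mean(rts) else NA_real_,
    latency_sd = if (length(rts) >= 2) sd(rts) else NA_real_,
    latency_cov = if (length(rts) >= 2) 100 * sd(rts) / mean(rts) else NA_real_
  )
  attr(out, "latency_defined") <- has_rt
  out
}

#' Build per-epoch performance features
#'
#' Divides the session into fixed-length epochs by trial onset time and
#' summarizes each epoch with the feature vector used by the
#' attention-state classifier: hit rate, false-alarm rate, mean correct
#' RT, RT standard deviation and response count.  A trailing partial
#' epoch shorter than half the epoch length is dropped; epochs without
#' trials are zero-filled and flagged.
#'
#' @param responses Response data frame.
#' @param epoch_length Epoch length in seconds (default 30).
#' @param session_duration Session length in seconds (default: inferred
#'   from the last trial).
#' @return Data frame of class `epoch_features`: `epoch`, `hit_rate`,
#'   `fa_rate`, `rt_mean`, `rt_sd`, `n_responses`, `empty`.
#' @export
build_epoch_features <- function(responses, epoch_length = 30,
                                 session_duration = NULL) {
  if (is.null(session_duration)) {
    session_duration <- attr(responses, "session_duration")
    if (is.null(session_duration))
      session_duration <- max(responses$onset_ms) / 1000
  }
  if (session_duration < epoch_length) stop("session shorter than one epoch")
  n_epochs <- floor(session_duration / epoch_length)
  remainder <- session_duration - n_epochs * epoch_length
  if (remainder >= epoch_length / 2) n_epochs <- n_epochs + 1L
  epoch <- floor(responses$onset_ms / 1000 / epoch_length) + 1L
  keep <- epoch <= n_epochs
  responses <- responses[keep, ]; epoch <- epoch[keep]
  rows <- lapply(seq_len(n_epochs), function(e) {
    r <- responses[epoch == e, ]
    if (nrow(r) == 0)
      return(data.frame(epoch = e, hit_rate = 0, fa_rate = 0, rt_mean = 0,
                        rt_sd = 0, n_responses = 0, empty = TRUE))
    tgt <- r$is_target
    rts <- r$rt_ms[r$responded & !is.na(r$rt_ms)]
    data.frame(
      epoch = e,
      hit_rate = if (any(tgt)) mean(r$responded[tgt]) else 0,
      fa_rate = if (any(!tgt)) mean(r$responded[!tgt]) else 0,
      rt_mean = if (length(rts)) mean(rts) else 0,
      rt_sd = if (length(rts) >= 2) sd(rts) else 0,
      n_responses = sum(r$responded),
      empty = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("epoch_features", "data.frame")
  out
}

epoch_feature_names <- function() {
  c("hit_rate", "fa_rate", "rt_mean", "rt_sd", "n_responses")
}

#' Fit the attention-state epoch classifier
#'
#' Multiclass Fisher linear discriminant (pooled within-class covariance,
#' via \code{MASS::lda}) mapping epoch feature vectors to the five
#' attention states.  Training data must contain every state.
#'
#' @param features Epoch feature data frame (see
#'   [build_epoch_features()]).
#' @param labels Character/factor vector of hidden state labels.
#' @param priors Class prior probabilities (default uniform, so
#'   classification is by Fisher discriminant score alone).
#' @return An object of class `state_classifier`.
#' @export
fit_state_lda <- function(features, labels,
                          priors = rep(1 / 5, 5)) {
  states <- attention_states()
  labels <- as.character(labels)
  missing_states <- setdiff(states, unique(labels))
  if (length(missing_states))
    stop("training data lacks states: ", paste(missing_states, collapse = ", "))
  x <- as.matrix(features[, epoch_feature_names()])
  fit <- MASS::lda(x, grouping = factor(labels, levels = states),
                   prior = priors)
  structure(list(lda = fit, states = states,
                 feature_names = epoch_feature_names()),
            class = "state_classifier")
}

#' Classify epochs into attention states
#'
#' Assigns each epoch the state with maximal discriminant posterior.
#' Exact posterior ties are broken by the fixed state priority
#' attentive > distracted > impulsive > random > minimal.
#'
#' @param classifier A [fit_state_lda()] model.
#' @param features Epoch feature data frame.
#' @return The feature frame with `state` (factor) and per-state
#'   posterior columns appended.
#' @export
classify_epochs <- function(classifier, features) {
  stopifnot(inherits(classifier, "state_classifier"))
  x <- as.matrix(features[, classifier$feature_names])
  post <- predict(classifier$lda, x)$posterior
  # priority-ordered argmax: ties fall to the earlier (higher-priority) state
  post_p <- post[, classifier$states, drop = FALSE]
  pick <- apply(post_p, 1, function(p) which(p >= max(p) - 1e-12)[1])
  features$state <- factor(classifier$states[pick],
                           levels = classifier$states)
  for (s in classifier$states)
    features[[paste0("post_", s)]] <- post_p[, s]
  features
}

#' Summarize an epoch state sequence
#'
#' Percent time in each state (labeled-epoch share x 100) and the number
#' of attention shifts, counted as adjacent-epoch label changes.
#'
#' @param states Factor/character vector of epoch state labels, or a
#'   classified epoch frame with a `state` column.
#' @return One-row data frame: `pct_attentive` ... `pct_minimal`,
#'   `attention_shifts`.
#' @export
summarize_states <- function(states) {
  if (is.data.frame(states)) states <- states$state
  states <- factor(as.character(states), levels = attention_states())
  if (anyNA(states)) stop("unknown state label")
  pct <- 100 * as.numeric(table(states)) / length(states)
  out <- as.data.frame(as.list(setNames(pct, paste0("pct_", attention_states()))))
  out$attention_shifts <- sum(head(states, -1) != tail(states, -1))
  out
}

# log-linear guard: clip a rate to [1/(2n), 1 - 1/(2n)]
clip_rate <- function(r, n) pmin(pmax(r, 1 / (2 * n)), 1 - 1 / (2 * n))

#' Score the letter-CPT battery
#'
#' Computes the twelve reported letter-CPT measures: errors of omission
#' and commission, correct-response RT and its standard error, RT
#' variability across sub-blocks, signal-detection discriminability
#' d' = z(hit) - z(fa) and response bias
#' beta = exp((z(fa)^2 - z(hit)^2) / 2) with rates clipped to
#' `[1/(2N), 1 - 1/(2N)]`, perseverations (responses under 100 ms), and
#' least-squares slopes of mean correct RT and of RT standard error
#' against block index (1-6) and against ISI level index (1-3).
#'
#' @param responses Letter-CPT response data frame with `block`,
#'   `sub_block`, `isi_ms` columns.
#' @return One-row data frame with the measures named as in
#'   [calibration_table()] (prefix `cpt_`).  With no responses the
#'   signal-detection fields are `NA` and the `sdt_defined` attribute is
#'   `FALSE`.
#' @export
score_cptii <- function(responses) {
  stopifnot(all(c("block", "sub_block", "isi_ms") %in% names(responses)))
  tgt <- responses$is_target
  n_t <- sum(tgt); n_nt <- sum(!tgt)
  eom <- sum(tgt & !responses$responded)
  eoc <- sum(!tgt & responses$responded)
  correct_rt <- responses$rt_ms[tgt & responses$responded & !is.na(responses$rt_ms)]
  any_resp <- any(responses$responded)
  if (any_resp && n_t > 0 && n_nt > 0) {
    zh <- qnorm(clip_rate(mean(responses$responded[tgt]), n_t))
    zf <- qnorm(clip_rate(mean(responses$responded[!tgt]), n_nt))
    d_prime <- zh - zf
    beta <- exp((zf^2 - zh^2) / 2)
  } else {
    d_prime <- NA_real_; beta <- NA_real_
  }
  persev <- sum(responses$responded & !is.na(responses$rt_ms) &
                  responses$rt_ms < 100)
  # per sub-block correct-RT summaries
  sb <- split(responses, list(responses$block, responses$sub_block), drop = TRUE)
  sb_stats <- do.call(rbind, lapply(sb, function(r) {
    rts <- r$rt_ms[r$is_target & r$responded & !is.na(r$rt_ms)]
    data.frame(block = r$block[1], isi_ms = r$isi_ms[1],
               rt_mean = if (length(rts)) mean(rts) else NA_real_,
               rt_sd = if (length(rts) >= 2) sd(rts) else NA_real_,
               rt_se = if (length(rts) >= 2) sd(rts) / sqrt(length(rts)) else NA_real_)
  }))
  block_var <- {
    s <- sb_stats$rt_sd[!is.na(sb_stats$rt_sd)]
    if (length(s) >= 2) sd(s) else NA_real_
  }
  slope_of <- function(xs, ys) {
    ok <- !is.na(ys)
    if (sum(ok) >= 2 && length(unique(xs[ok])) >= 2) ls_slope(xs[ok], ys[ok])
    else NA_real_
  }
  isi_index <- match(sb_stats$isi_ms, sort(unique(sb_stats$isi_ms)))
  out <- data.frame(
    cpt_eom = eom, cpt_eoc = eoc,
    cpt_rt = if (length(correct_rt)) mean(correct_rt) else NA_real_,
    cpt_rt_se = if (length(correct_rt) >= 2)
      sd(correct_rt) / sqrt(length(correct_rt)) else NA_real_,
    cpt_rt_block_var = block_var,
    cpt_dprime = d_prime, cpt_beta = beta,
    cpt_perseverations = persev,
    cpt_rt_slope_blocks = slope_of(sb_stats$block, sb_stats$rt_mean),
    cpt_rt_se_slope_blocks = slope_of(sb_stats$block, sb_stats$rt_se),
    cpt_rt_slope_isi = slope_of(isi_index, sb_stats$rt_mean),
    cpt_rt_se_slope_isi = slope_of(isi_index, sb_stats$rt_se)
  )
  attr(out, "sdt_defined") <- any_resp && n_t > 0 && n_nt > 0
  out
}
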