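#' Simulate a high-target-density cognitive control stimulus stream
#'
#' Generates the trial schedule of a "respond to everything except the
#' 4-pointed star" task: star stimuli (16/8/5/4 points) shown for 240 ms
#' at random screen positions, ~90% targets, with a variable
#' interstimulus interval averaging 2500 ms.  The ISI is drawn from a
#' shifted exponential (minimum 1000 ms, mean 2500 ms); the task length
#' defaults to a 20-minute session, giving about 438 trials.
#'
#' @param session_duration Session length in seconds (default 1200).
#' @param seed Integer seed.
#' @param target_fraction Target share of trials (default 0.9).
#' @param stimulus_ms Stimulus duration in ms (default 240).
#' @param isi_mean_ms,isi_min_ms ISI mean and minimum in ms.
#' @return A data frame of class `trial_stream` with columns `task`,
#'   `trial_index`, `onset_ms`, `stimulus_code` (star points), `is_target`,
#'   `isi_ms`.
#' @export
simulate_no4s_stream <- function(session_duration = 1200, seed = 1,
                                 target_fraction = 0.9, stimulus_ms = 240,
                                 isi_mean_ms = 2500, isi_min_ms = 1000) {
  stopifnot(session_duration > 0, isi_mean_ms > isi_min_ms)
  set.seed(seed)
  end_ms <- session_duration * 1000
  # generous trial budget, then truncate at session end
  n_max <- ceiling(end_ms / (stimulus_ms + isi_min_ms)) + 10
  isi <- isi_min_ms + rexp(n_max, 1 / (isi_mean_ms - isi_min_ms))
  onset <- cumsum(c(0, stimulus_ms + isi))[seq_len(n_max)]
  keep <- onset + stimulus_ms <= end_ms
  onset <- onset[keep]
  n <- length(onset)
  is_target <- runif(n) >= 1 - target_fraction
  code <- ifelse(is_target, sample(c(16L, 8L, 5L), n, replace = TRUE), 4L)
  out <- data.frame(task = "no4s", trial_index = seq_len(n),
                    onset_ms = onset, stimulus_code = code,
                    is_target = is_target,
                    isi_ms = c(isi[seq_len(n - 1)], NA))
  attr(out, "session_duration") <- session_duration
  attr(out, "stimulus_ms") <- stimulus_ms
  class(out) <- c("trial_stream", "data.frame")
  out
}

#' Simulate a letter-CPT stimulus stream
#'
#' Generates the block structure of the letter continuous-performance
#' task: 6 blocks of 3 sub-blocks, one sub-block per ISI level (1000,
#' 2000, 4000 ms) in randomized order within block; letters shown for
#' 250 ms; the non-target letter 'X' appears at a configurable rate
#' (default 10%) with 20 trials per sub-block.
#'
#' @param seed Integer seed.
#' @param trials_per_subblock Trials per sub-block (default 20).
#' @param nontarget_rate Non-target share (default 0.1).
#' @param isi_levels_ms ISI levels in ms.
#' @param stimulus_ms Stimulus duration in ms (default 250).
#' @return A `trial_stream` data frame with columns `task`, `trial_index`,
#'   `onset_ms`, `stimulus_code` (letter), `is_target`, `block`,
#'   `sub_block`, `isi_ms`.
#' @export
simulate_cptii_stream <- function(seed = 1, trials_per_subblock = 20,
                                  nontarget_rate = 0.1,
                                  isi_levels_ms = c(1000, 2000, 4000),
                                  stimulus_ms = 250) {
  set.seed(seed)
  rows <- list()
  onset <- 0
  idx <- 1L
  for (b in 1:6) {
    isi_order <- sample(isi_levels_ms)
    for (s in 1:3) {
      isi <- isi_order[s]
      for (k in seq_len(trials_per_subblock)) {
        nt <- runif(1) < nontarget_rate
        rows[[idx]] <- data.frame(
          task = "cptii", trial_index = idx, onset_ms = onset,
          stimulus_code = if (nt) "X" else sample(setdiff(LETTERS, "X"), 1),
          is_target = !nt, block = b, sub_block = s, isi_ms = isi)
        onset <- onset + stimulus_ms + isi
        idx <- idx + 1L
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "session_duration") <- onset / 1000
  attr(out, "stimulus_ms") <- stimulus_ms
  class(out) <- c("trial_stream", "data.frame")
  out
}

#' Response model parameters
#'
#' Emission and transition structure of the hidden attention-state
#' response generator.  Within each 30-second epoch the subject occupies
#' one of five states (attentive, distracted, impulsive, random,
#' minimal); the state evolves across epochs by a Markov transition
#' matrix.  Each state has its own hit probability (response to a
#' target), false-alarm probability (response to a non-target) and
#' response-latency distribution.  Impulsive and random states can emit
#' anticipatory latencies below 100 ms.
#'
#' @param hit,fa Named numeric vectors of per-state hit/false-alarm
#'   probabilities.
#' @param rt_mean,rt_sd Named per-state latency mean and SD, ms.
#' @param transition 5x5 row-stochastic matrix (rows/cols in state order).
#' @param initial Initial state distribution.
#' @param anticipatory_prob Probability that an impulsive/random response
#'   is anticipatory (< 100 ms).
#' @return A list of class `response_model_params`.
#' @export
response_model_params <- function(
    hit = c(attentive = 0.99, distracted = 0.82, impulsive = 0.97,
            random = 0.50, minimal = 0.10),
    fa = c(attentive = 0.04, distracted = 0.30, impulsive = 0.85,
           random = 0.50, minimal = 0.05),
    rt_mean = c(attentive = 440, distracted = 580, impulsive = 310,
                random = 520, minimal = 660),
    rt_sd = c(attentive = 55, distracted = 130, impulsive = 60,
              random = 190, minimal = 150),
    transition = default_state_transition(),
    initial = c(attentive = 0.6, distracted = 0.15, impulsive = 0.2,
                random = 0.025, minimal = 0.025),
    anticipatory_prob = 0.12) {
  states <- attention_states()
  for (v in list(hit, fa, rt_mean, rt_sd, initial))
    stopifnot(identical(names(v), states))
  stopifnot(all(hit >= 0 & hit <= 1), all(fa >= 0 & fa <= 1),
            all(rt_sd >= 0), all(abs(rowSums(transition) - 1) < 1e-8),
            abs(sum(initial) - 1) < 1e-8)
  structure(list(hit = hit, fa = fa, rt_mean = rt_mean, rt_sd = rt_sd,
                 transition = transition, initial = initial,
                 anticipatory_prob = anticipatory_prob),
            class = "response_model_params")
}

#' @rdname response_model_params
#' @export
attention_states <- function() {
  c("attentive", "distracted", "impulsive", "random", "minimal")
}

#' @rdname response_model_params
#' @param stickiness Diagonal mass of the default transition matrix.
#' @export
default_state_transition <- function(stickiness = 0.55) {
  states <- attention_states()
  base <- c(attentive = 0.50, distracted = 0.22, impulsive = 0.22,
            random = 0.03, minimal = 0.03)
  tm <- matrix(rep(base * (1 - stickiness), 5), nrow = 5, byrow = TRUE,
               dimnames = list(states, states))
  diag(tm) <- diag(tm) + stickiness
  tm / rowSums(tm)
}

# stationary distribution of a row-stochastic matrix (leading left
# eigenvector)
stationary_distribution <- function(tm) {
  e <- eigen(t(tm))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

#' Simulate trial responses under hidden attention states
#'
#' Assigns each 30-second epoch a hidden attention state evolving by the
#' transition matrix, then emits one response record per trial according
#' to the state's hit/false-alarm probabilities and latency distribution.
#' Latencies are floored at 100 ms except for impulsive/random
#' anticipations, which fall in 40-99 ms and feed the downstream
#' perseveration count.  Hidden labels are returned for supervised
#' training and evaluation only.
#'
#' @param stream A `trial_stream` data frame.
#' @param params A [response_model_params()] object.
#' @param seed Integer seed.
#' @param epoch_length Epoch length in seconds (default 30).
#' @return List with `responses` (columns of `stream` plus `responded`,
#'   `rt_ms`) and `states` (per-epoch hidden labels).
#' @export
simulate_responses <- function(stream, params, seed = 1, epoch_length = 30) {
  stopifnot(nrow(stream) > 0, inherits(params, "response_model_params"))
  set.seed(seed)
  states <- attention_states()
  dur <- attr(stream, "session_duration")
  if (is.null(dur)) dur <- (max(stream$onset_ms) + 1000) / 1000
  n_epochs <- max(1L, ceiling(dur / epoch_length))
  state_seq <- character(n_epochs)
  state_seq[1] <- sample(states, 1, prob = params$initial)
  for (e in seq_len(n_epochs - 1L))
    state_seq[e + 1L] <- sample(states, 1, prob = params$transition[state_seq[e], ])
  epoch <- pmin(floor(stream$onset_ms / 1000 / epoch_length) + 1L, n_epochs)
  st <- state_seq[epoch]
  p_resp <- ifelse(stream$is_target, params$hit[st], params$fa[st])
  responded <- runif(nrow(stream)) < p_resp
  rt <- rep(NA_real_, nrow(stream))
  if (any(responded)) {
    mu <- params$rt_mean[st[responded]]
    s <- params$rt_sd[st[responded]]
    r <- pmax(rnorm(sum(responded), mu, s), 100)
    anticip <- st[responded] %in% c("impulsive", "random") &
      runif(sum(responded)) < params$anticipatory_prob
    r[anticip] <- runif(sum(anticip), 40, 99)
    rt[responded] <- r
  }
  responses <- stream
  responses$responded <- responded
  responses$rt_ms <- rt
  class(responses) <- "data.frame"
  list(responses = responses,
       states = data.frame(epoch = seq_len(n_epochs), state = state_seq))
}

#' Write / read a trial response log
#'
#' CSV interchange format for trial-level response logs with columns
#' `task`, `trial_index`, `onset_ms`, `stimulus_code`, `is_target`,
#' `responded`, `rt_ms` and, for the letter CPT, `block`, `sub_block`,
#' `isi_ms`.
#'
#' @param responses Response data frame.
#' @param path File path.
#' @return `read_response_csv` returns the response data frame.
#' @export
write_response_csv <- function(responses, path) {
  write.csv(responses, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_response_csv
#' @export
read_response_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("task", "trial_index", "onset_ms", "is_target", "responded")
  if (!all(required %in% names(out)))
    stop("response log lacks columns: ",
         paste(setdiff(required, names(out)), collapse = ", "))
  out$is_target <- as.logical(out$is_target)
  out$responded <- as.logical(out$responded)
  out
}
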