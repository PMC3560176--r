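#' Movement model parameters
#'
#' Parameters of the bout/immobility trajectory generator.  A tracked
#' marker alternates between heavy-tailed still periods and short movement
#' bouts realized as correlated 2-D walks.  The generator is plumbing used
#' to exercise the motion-feature extractors: its parameters control the
#' ranges of the downstream measures, they are not published quantities.
#'
#' @param bout_rate Movement bouts per minute (>= 0).
#' @param bout_amplitude_scale Typical bout path length, mm.
#' @param immobility_tail_exponent Pareto tail index of still-period
#'   durations (> 1 so the mean exists; smaller = heavier tail).
#' @param path_roughness In `[0, 1]`: 0 gives straight bouts, 1 maximally
#'   jittered (isotropic turning).
#' @param sampling_rate Frames per second (default 50, the camera rate).
#' @param resolution Spatial quantization, mm (default 0.04, the camera
#'   resolution).
#' @param session_duration Session length in seconds.
#' @param bout_duration Nominal bout length in seconds.
#' @return A list of class `movement_model_params`.
#' @export
movement_model_params <- function(bout_rate = 10, bout_amplitude_scale = 8,
                                  immobility_tail_exponent = 1.8,
                                  path_roughness = 0.5,
                                  sampling_rate = 50, resolution = 0.04,
                                  session_duration = 1200,
                                  bout_duration = 0.6) {
  stopifnot(bout_rate >= 0, sampling_rate > 0, resolution > 0,
            session_duration > 0, immobility_tail_exponent > 1,
            path_roughness >= 0, path_roughness <= 1, bout_duration > 0)
  structure(list(bout_rate = bout_rate,
                 bout_amplitude_scale = bout_amplitude_scale,
                 immobility_tail_exponent = immobility_tail_exponent,
                 path_roughness = path_roughness,
                 sampling_rate = sampling_rate, resolution = resolution,
                 session_duration = session_duration,
                 bout_duration = bout_duration),
            class = "movement_model_params")
}

# Pareto draw with tail index alpha and minimum xm
rpareto <- function(n, alpha, xm) xm * runif(n)^(-1 / alpha)

#' Simulate a marker trajectory
#'
#' Generates a quantized 2-D marker path at the camera's sampling rate:
#' still periods with Pareto-distributed durations alternate with movement
#' bouts simulated as correlated random walks whose turning-angle
#' dispersion is set by `path_roughness`.  Coordinates are quantized to
#' the camera resolution, so genuine stillness is exactly constant.
#'
#' @param params A [movement_model_params()] object.
#' @param marker_id Marker label (`"head"`, `"left_shin"`, `"right_shin"`).
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @return A data frame of class `trajectory` with columns `marker_id`,
#'   `frame_index`, `time_s`, `x_mm`, `y_mm`, `valid`, and a `bouts`
#'   attribute logging each planted bout (start/end time, path length).
#' @export
simulate_trajectory <- function(params, marker_id = "head", seed = 1) {
  stopifnot(inherits(params, "movement_model_params"))
  set.seed(seed)
  fs <- params$sampling_rate
  n <- round(params$session_duration * fs)
  x <- numeric(n); y <- numeric(n)
  bouts <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      path_mm = numeric(0))
  if (params$bout_rate > 0) {
    nb_frames <- max(2L, round(params$bout_duration * fs))
    # mean still gap chosen so bouts occur at the requested rate
    gap_mean <- max(60 / params$bout_rate - params$bout_duration, 0.02)
    alpha <- params$immobility_tail_exponent
    xm <- gap_mean * (alpha - 1) / alpha
    pos <- c(0, 0)
    frame <- 1L
    while (frame <= n) {
      gap <- rpareto(1, alpha, xm)
      still_frames <- min(n - frame + 1L, max(1L, round(gap * fs)))
      idx <- frame:(frame + still_frames - 1L)
      x[idx] <- pos[1]; y[idx] <- pos[2]
      frame <- frame + still_frames
      if (frame > n) break
      # movement bout: correlated walk, step length jittered around the
      # amplitude scale divided across the bout
      k <- min(nb_frames, n - frame + 1L)
      step <- params$bout_amplitude_scale / nb_frames *
        rexp(k)  # irregular step lengths
      kappa <- pi * params$path_roughness
      turn <- rnorm(k, 0, kappa)
      heading <- runif(1, 0, 2 * pi) + cumsum(turn)
      dx <- step * cos(heading); dy <- step * sin(heading)
      idx <- frame:(frame + k - 1L)
      x[idx] <- pos[1] + cumsum(dx)
      y[idx] <- pos[2] + cumsum(dy)
      bouts <- rbind(bouts, data.frame(
        start_s = (frame - 1L) / fs, end_s = (frame + k - 2L) / fs,
        path_mm = sum(step)))
      pos <- c(x[idx[k]], y[idx[k]])
      frame <- frame + k
    }
  }
  res <- params$resolution
  traj <- data.frame(
    marker_id = marker_id,
    frame_index = seq_len(n) - 1L,
    time_s = (seq_len(n) - 1L) / fs,
    x_mm = round(x / res) * res,
    y_mm = round(y / res) * res,
    valid = 1L
  )
  attr(traj, "bouts") <- bouts
  attr(traj, "sampling_rate") <- fs
  attr(traj, "resolution") <- res
  class(traj) <- c("trajectory", "data.frame")
  traj
}

#' Inject frame loss into a trajectory
#'
#' Marks frames invalid in temporally contiguous runs, mimicking marker
#' occlusions and reflections.  Run structure is a two-state Markov chain
#' with geometric invalid-run lengths (mean `run_length` frames) whose
#' stationary invalid share equals `loss_fraction`; valid positions are
#' left untouched.
#'
#' @param traj A `trajectory` data frame.
#' @param loss_fraction Expected share of invalid frames, in `[0, 1)`.
#' @param seed Integer seed.
#' @param run_length Mean invalid-run length in frames (default 10).
#' @return The trajectory with its `valid` column updated.
#' @export
inject_frame_loss <- function(traj, loss_fraction, seed = 1, run_length = 10) {
  if (loss_fraction < 0 || loss_fraction >= 1)
    stop("loss_fraction must be in [0, 1)")
  if (loss_fraction == 0) return(traj)
  set.seed(seed)
  n <- nrow(traj)
  p_rec <- 1 / run_length                       # invalid -> valid
  p_loss <- p_rec * loss_fraction / (1 - loss_fraction)  # valid -> invalid
  # vectorized chain: simulate alternating run lengths
  state <- runif(1) < loss_fraction
  runs <- list(); total <- 0L; i <- 1L
  while (total < n) {
    len <- rgeom(1, if (state) p_rec else p_loss) + 1L
    runs[[i]] <- rep(if (state) 0L else 1L, len)
    total <- total + len; i <- i + 1L
    state <- !state
  }
  traj$valid <- unlist(runs)[seq_len(n)]
  traj
}

#' Write / read trajectory TSV
#'
#' Plain-text interchange format for marker trajectories: tab-separated
#' columns `marker_id`, `frame_index`, `time_s`, `x_mm`, `y_mm`, `valid`.
#'
#' @param traj A trajectory data frame.
#' @param path File path.
#' @return `read_trajectory_tsv` returns a `trajectory` data frame.
#' @export
write_trajectory_tsv <- function(traj, path) {
  utils::write.table(as.data.frame(traj)[, c("marker_id", "frame_index",
                                             "time_s", "x_mm", "y_mm", "valid")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_tsv
#' @export
read_trajectory_tsv <- function(path) {
  traj <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("marker_id", "frame_index", "time_s", "x_mm", "y_mm", "valid")
  if (!all(required %in% names(traj)))
    stop("trajectory file lacks columns: ",
         paste(setdiff(required, names(traj)), collapse = ", "))
  class(traj) <- c("trajectory", "data.frame")
  traj
}
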