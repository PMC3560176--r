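#' Clean a trajectory and measure its frame loss
#'
#' Fills invalid frames by linear interpolation between the nearest valid
#' neighbours (leading/trailing gaps are held at the nearest valid
#' position) and reports the invalid share, which downstream
#' [adjust_for_loss()] uses to rescale the extensive measures.
#'
#' @param traj A `trajectory` data frame with a 0/1 `valid` column.
#' @return List with components `trajectory` (all frames valid) and
#'   `loss_fraction`.
#' @export
preprocess_trajectory <- function(traj) {
  v <- traj$valid == 1
  if (sum(v) < 2) stop("need at least 2 valid frames")
  loss <- mean(!v)
  if (loss > 0) {
    t_ok <- traj$time_s[v]
    traj$x_mm <- approx(t_ok, traj$x_mm[v], xout = traj$time_s, rule = 2)$y
    traj$y_mm <- approx(t_ok, traj$y_mm[v], xout = traj$time_s, rule = 2)$y
    traj$valid <- 1L
  }
  list(trajectory = traj, loss_fraction = loss)
}

# event times at which the marker's distance from a moving anchor first
# reaches `threshold`; the anchor jumps to the current position at each
# event.  Shared by the microevent count, immobility statistics and the
# temporal scaling exponent.
microevent_times <- function(traj, threshold = 1.0) {
  x <- traj$x_mm; y <- traj$y_mm; n <- length(x)
  times <- numeric(0)
  if (n < 2) return(times)
  ax <- x[1]; ay <- y[1]
  th2 <- threshold^2
  ev <- vector("list", 64L); k <- 0L
  i <- 2L
  while (i <= n) {
    if ((x[i] - ax)^2 + (y[i] - ay)^2 >= th2) {
      k <- k + 1L
      if (k > length(ev)) ev <- c(ev, vector("list", length(ev)))
      ev[[k]] <- traj$time_s[i]
      ax <- x[i]; ay <- y[i]
    }
    i <- i + 1L
  }
  if (k == 0L) numeric(0) else unlist(ev[seq_len(k)])
}

#' Count movement microevents
#'
#' A microevent fires whenever the marker has moved at least `threshold`
#' millimetres from an anchor position; the anchor then resets to the
#' current position.  The anchored definition is robust to sub-resolution
#' jitter, which oscillates without ever escaping the anchor
#' neighbourhood.
#'
#' @param traj A cleaned trajectory.
#' @param threshold Displacement threshold in mm (default 1, the
#'   "movements > 1 mm" convention).
#' @return Integer event count.
#' @export
count_microevents <- function(traj, threshold = 1.0) {
  length(microevent_times(traj, threshold))
}

#' Total path displacement
#'
#' Sum of inter-frame Euclidean distances, reported in metres.
#'
#' @param traj A cleaned trajectory.
#' @return Displacement in m.
#' @export
total_displacement <- function(traj) {
  dx <- diff(traj$x_mm); dy <- diff(traj$y_mm)
  sum(sqrt(dx^2 + dy^2)) / 1000
}

#' Area in which the movements occurred
#'
#' Convex-hull area of the visited positions, reported in cm^2.
#' Degenerate (collinear) point sets have zero area.
#'
#' @param traj A cleaned trajectory.
#' @return Area in cm^2.
#' @export
movement_area <- function(traj) {
  pts <- unique(cbind(traj$x_mm, traj$y_mm))
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts)
  hx <- pts[h, 1]; hy <- pts[h, 2]
  # shoelace formula, mm^2 -> cm^2
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2 / 100
}

#' Mean immobility duration
#'
#' Still periods are the gaps between consecutive microevents (plus the
#' leading and trailing event-free segments); with no events the whole
#' session counts as a single still period.  Returns the mean still
#' duration in seconds.
#'
#' @param traj A cleaned trajectory.
#' @param threshold Microevent threshold in mm.
#' @return Mean still-period duration, s.
#' @export
immobility_statistics <- function(traj, threshold = 1.0) {
  span <- diff(range(traj$time_s))
  ev <- microevent_times(traj, threshold)
  if (length(ev) == 0) return(span)
  gaps <- diff(c(traj$time_s[1], ev, traj$time_s[length(traj$time_s)]))
  mean(gaps)
}

# least-squares slope of y on x
ls_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * (y - mean(y))) / sum(xc^2)
}

#' Spatial scaling exponent (path complexity)
#'
#' Divider (compass) dimension of the 2-D movement path: the apparent
#' path length `L(r)` is measured by walking the path with ruler size `r`
#' over a geometric ladder of rulers; the exponent is `1 - slope` of
#' `log L(r)` versus `log r`, clamped to `[1, 2]`.  A straight path gives
#' 1; an erratic, plane-filling path approaches 2.
#'
#' @param traj A cleaned trajectory with positive path length.
#' @param rulers Optional ruler ladder in mm; by default `0.5 * 2^k`
#'   capped at one quarter of the bounding-box diagonal.
#' @return Exponent in `[1, 2]`.
#' @export
spatial_complexity <- function(traj, rulers = NULL) {
  xy <- cbind(traj$x_mm, traj$y_mm)
  keep <- c(TRUE, rowSums(abs(diff(xy))) > 0)  # drop repeated frames
  xy <- xy[keep, , drop = FALSE]
  if (nrow(xy) < 2 || total_displacement(traj) <= 0)
    stop("spatial complexity undefined for a zero-length path")
  if (is.null(rulers)) {
    extent <- sqrt(diff(range(xy[, 1]))^2 + diff(range(xy[, 2]))^2)
    steps <- sqrt(rowSums(diff(xy)^2))
    # inner cutoff: twice the mean inter-vertex step (floored at 0.5 mm)
    # so the ladder tracks the path's own scale and the exponent is
    # invariant under uniform rescaling
    r0 <- max(0.5, 2 * mean(steps[steps > 0]))
    rulers <- r0 * 2^(0:12)
    rulers <- rulers[rulers <= max(extent / 4, 2 * r0)]
  }
  if (length(rulers) < 3) rulers <- rulers[1] * 2^(0:2)
  lens <- vapply(rulers, function(r) divider_length(xy, r), numeric(1))
  ok <- lens > 0
  if (sum(ok) < 2) return(1)
  slope <- ls_slope(log(rulers[ok]), log(lens[ok]))
  min(max(1 - slope, 1), 2)
}

# apparent path length at ruler r: true compass walk.  The compass point
# is placed where the circle of radius r around the current anchor first
# intersects the polyline (interpolating within segments), so each step
# contributes exactly r; the remainder to the path end closes the sum.
divider_length <- function(xy, r) {
  n <- nrow(xy)
  x <- xy[, 1]; y <- xy[, 2]
  ax <- x[1]; ay <- y[1]
  r2 <- r^2
  steps <- 0
  px <- x[1]; py <- y[1]  # current position along the path
  i <- 2L
  while (i <= n) {
    qx <- x[i]; qy <- y[i]
    if ((qx - ax)^2 + (qy - ay)^2 < r2) {
      # segment end still inside the compass circle: advance
      px <- qx; py <- qy
      i <- i + 1L
      next
    }
    # first crossing of the circle on segment (p, q)
    dx <- qx - px; dy <- qy - py
    fx <- px - ax; fy <- py - ay
    a2 <- dx^2 + dy^2
    b <- 2 * (fx * dx + fy * dy)
    c0 <- fx^2 + fy^2 - r2
    disc <- b^2 - 4 * a2 * c0
    t <- if (disc <= 0 || a2 == 0) 1 else (-b + sqrt(disc)) / (2 * a2)
    t <- min(max(t, 0), 1)
    px <- px + t * dx; py <- py + t * dy
    ax <- px; ay <- py
    steps <- steps + 1
    # stay on this segment; further steps may fit before reaching q
  }
  steps * r + sqrt((x[n] - ax)^2 + (y[n] - ay)^2)
}

#' Temporal scaling exponent (activity pervasiveness)
#'
#' Box-counting exponent of the microevent point process in time: the
#' number of occupied time boxes `N(w)` is counted over a geometric ladder
#' of widths, and the exponent is `-slope` of `log N(w)` versus `log w`,
#' clamped to `[0, 1]`.  An event in every bin at every width gives 1
#' (pervasive activity); no events give 0 by convention; clustered sparse
#' activity falls in between.  Widths at which the count saturates at the
#' number of events carry no scaling information and are excluded from
#' the fit.
#'
#' @param traj A cleaned trajectory.
#' @param threshold Microevent threshold in mm.
#' @param widths Box-width ladder in seconds (default `0.5 * 2^(0:7)`,
#'   i.e. 0.5 s to 64 s).
#' @return Exponent in `[0, 1]`.
#' @export
temporal_scaling <- function(traj, threshold = 1.0, widths = 0.5 * 2^(0:7)) {
  ev <- microevent_times(traj, threshold)
  temporal_boxcount_exponent(ev, widths)
}

#' @rdname temporal_scaling
#' @param event_times Event time stamps in seconds (for direct use on a
#'   point process).
#' @export
temporal_boxcount_exponent <- function(event_times, widths = 0.5 * 2^(0:7)) {
  if (length(event_times) == 0) return(0)
  counts <- vapply(widths, function(w)
    length(unique(floor(event_times / w))), numeric(1))
  ok <- counts < length(event_times) | counts == 1
  ok <- ok & counts >= 1
  if (sum(ok) < 2) {
    # saturated at every width: fall back to the full ladder
    ok <- rep(TRUE, length(widths))
  }
  slope <- ls_slope(log(widths[ok]), log(counts[ok]))
  min(max(-slope, 0), 1)
}

#' Extract the full movement feature set
#'
#' Runs [preprocess_trajectory()] and all six movement measures on a raw
#' trajectory, then applies the frame-loss adjustment.
#'
#' @param traj A raw `trajectory` (may contain invalid frames).
#' @param threshold Microevent threshold, mm.
#' @return A one-row data frame of class `motion_feature_set`:
#'   `immobility_duration` (s), `microevents`, `displacement` (m),
#'   `area` (cm^2), `spatial_complexity`, `temporal_scaling`,
#'   `loss_fraction`.
#' @export
motion_features <- function(traj, threshold = 1.0) {
  pre <- preprocess_trajectory(traj)
  clean <- pre$trajectory
  feats <- data.frame(
    immobility_duration = immobility_statistics(clean, threshold),
    microevents = count_microevents(clean, threshold),
    displacement = total_displacement(clean),
    area = movement_area(clean),
    spatial_complexity = if (total_displacement(clean) > 0)
      spatial_complexity(clean) else NA_real_,
    temporal_scaling = temporal_scaling(clean, threshold),
    loss_fraction = pre$loss_fraction
  )
  class(feats) <- c("motion_feature_set", "data.frame")
  adjust_for_loss(feats, pre$loss_fraction)
}

#' Adjust extensive movement measures for frame loss
#'
#' Scales the extensive measures (microevents, displacement) by
#' `1 / (1 - loss_fraction)`; intensive measures (scaling exponents,
#' area, mean immobility) are left untouched.  Heavy loss (>= 50%) is
#' flagged with a warning as a data-quality concern.
#'
#' @param features A `motion_feature_set` row.
#' @param loss_fraction Invalid-frame share in `[0, 1)`.
#' @return The adjusted feature set, with an `loss_adjusted` attribute.
#' @export
adjust_for_loss <- function(features, loss_fraction) {
  if (loss_fraction < 0 || loss_fraction >= 1)
    stop("loss_fraction must be in [0, 1)")
  if (loss_fraction >= 0.5)
    warning("frame loss of ", round(100 * loss_fraction),
            "% exceeds 50%; extracted features are unreliable")
  scale <- 1 / (1 - loss_fraction)
  features$microevents <- features$microevents * scale
  features$displacement <- features$displacement * scale
  attr(features, "loss_adjusted") <- loss_fraction > 0
  features
}
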