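# shared fixtures and independent oracles

make_traj <- function(x, y, fs = 50, marker = "head") {
  d <- data.frame(marker_id = marker, frame_index = seq_along(x) - 1L,
                  time_s = (seq_along(x) - 1L) / fs, x_mm = x, y_mm = y,
                  valid = 1L)
  class(d) <- c("trajectory", "data.frame")
  d
}

# exhaustive pair-counting AUC: concordant pairs + half ties
auc_pair_oracle <- function(scores, positive) {
  diffs <- outer(scores[positive], scores[!positive], "-")
  (sum(diffs > 0) + 0.5 * sum(diffs == 0)) / length(diffs)
}

# grid box-counting dimension of a planar point set
boxcount_dimension <- function(xy, sizes) {
  ns <- vapply(sizes, function(s)
    nrow(unique(cbind(floor(xy[, 1] / s), floor(xy[, 2] / s)))), numeric(1))
  fit <- lm(log(ns) ~ log(sizes))
  -unname(coef(fit)[2])
}

# triadic Koch curve vertices (fractal dimension log4 / log3)
koch_curve <- function(depth, scale = 100) {
  pts <- matrix(c(0, 0, 1, 0), ncol = 2, byrow = TRUE)
  for (d in seq_len(depth)) {
    out <- vector("list", nrow(pts) - 1L)
    for (i in seq_len(nrow(pts) - 1L)) {
      a <- pts[i, ]; b <- pts[i + 1L, ]; v <- (b - a) / 3
      p1 <- a + v; p3 <- a + 2 * v
      p2 <- p1 + c(v[1] * cos(pi / 3) - v[2] * sin(pi / 3),
                   v[1] * sin(pi / 3) + v[2] * cos(pi / 3))
      out[[i]] <- rbind(a, p1, p2, p3)
    }
    pts <- rbind(do.call(rbind, out), pts[nrow(pts), ])
  }
  pts * scale
}

# middle-thirds Cantor point set on [0, 3^depth] (dimension log2 / log3)
cantor_times <- function(depth) {
  t <- 0
  for (i in seq_len(depth)) t <- c(t, t + 2 * 3^(i - 1))
  sort(t)
}

worked_log <- function() {
  path <- system.file("extdata", "no4s_worked_log.csv", package = "sitstill")
  read_response_csv(path)
}

# dense isotropic random walk trajectory
random_walk_traj <- function(n = 8000, step = 0.8, seed = 4) {
  set.seed(seed)
  ang <- runif(n, 0, 2 * pi)
  make_traj(cumsum(step * cos(ang)), cumsum(step * sin(ang)))
}
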