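test_that("preprocessing interpolates lost frames linearly", {
  tr <- make_traj(c(0, 1, 2), c(0, 1, 2))
  out <- preprocess_trajectory(tr)
  expect_identical(out$trajectory$x_mm, tr$x_mm)
  expect_equal(out$loss_fraction, 0)

  tr2 <- make_traj(c(0, 99, 2), c(0, 99, 2))
  tr2$valid <- c(1L, 0L, 1L)
  out2 <- preprocess_trajectory(tr2)
  expect_equal(out2$trajectory$x_mm[2], 1)
  expect_equal(out2$trajectory$y_mm[2], 1)
  expect_equal(out2$loss_fraction, 1 / 3)

  expect_error(preprocess_trajectory(make_traj(0, 0)), "valid frames")
})

test_that("interpolation is exact on a straight path under 18% loss", {
  n <- 5000
  tr <- make_traj(seq(0, 200, length.out = n), seq(0, 100, length.out = n))
  set.seed(12)
  tr$valid <- as.integer(runif(n) > 0.18)
  tr$valid[c(1, n)] <- 1L
  clean <- preprocess_trajectory(tr)$trajectory
  ref <- total_displacement(make_traj(seq(0, 200, length.out = n),
                                      seq(0, 100, length.out = n)))
  expect_lt(abs(total_displacement(clean) / ref - 1), 0.001)
})

test_that("microevents count anchored threshold crossings", {
  expect_equal(count_microevents(make_traj(rep(0, 100), rep(0, 100))), 0)
  # ten isolated 2-mm jumps separated by stillness
  jumps <- rep(seq(0, 20, by = 2), each = 10)
  expect_equal(count_microevents(make_traj(jumps, rep(0, length(jumps)))), 10)
  # monotone 25.5-mm drift in 0.5-mm steps: one event per accumulated mm
  drift <- seq(0, 25.5, by = 0.5)
  expect_equal(count_microevents(make_traj(drift, rep(0, length(drift)))), 25)
  # brute-force anchored oracle on a seeded jitter path
  set.seed(33)
  x <- cumsum(rnorm(2000, 0, 0.4)); y <- cumsum(rnorm(2000, 0, 0.4))
  oracle <- local({
    cnt <- 0L; ax <- x[1]; ay <- y[1]
    for (i in 2:length(x))
      if (sqrt((x[i] - ax)^2 + (y[i] - ay)^2) >= 1) {
        cnt <- cnt + 1L; ax <- x[i]; ay <- y[i]
      }
    cnt
  })
  expect_equal(count_microevents(make_traj(x, y)), oracle)
})

test_that("displacement and area recover elementary geometry", {
  sq <- make_traj(c(0, 10, 10, 0, 0), c(0, 0, 10, 10, 0))
  expect_equal(total_displacement(sq), 0.04)     # 40 mm perimeter in m
  expect_equal(movement_area(sq), 1)             # 100 mm^2 = 1 cm^2
  line <- make_traj(seq(0, 50, 1), seq(0, 50, 1))
  expect_equal(movement_area(line), 0)
  th <- seq(0, 2 * pi, length.out = 1001)
  disc <- make_traj(20 * cos(th), 20 * sin(th))
  expect_lt(abs(movement_area(disc) / (pi * 4) - 1), 0.01)
  expect_equal(total_displacement(make_traj(rep(1, 10), rep(1, 10))), 0)
})

test_that("immobility statistics summarize still-period durations", {
  still <- make_traj(rep(0, 15000), rep(0, 15000))
  expect_equal(immobility_statistics(still), 299.98)  # whole session
  # an event every 2 s: 2-mm jump each 100 frames
  x <- rep(seq(0, 2 * 149, by = 2), each = 100)
  expect_lt(abs(immobility_statistics(make_traj(x, rep(0, length(x)))) - 2), 0.05)
  # continuous large-amplitude motion approaches one frame interval
  big <- make_traj(seq(0, 2 * 4999, by = 2), rep(0, 5000))
  expect_lt(immobility_statistics(big), 0.021)
})

test_that("spatial complexity hits analytic dimensions", {
  line <- make_traj(seq(0, 100, length.out = 2000), seq(0, 100, length.out = 2000))
  expect_lt(abs(spatial_complexity(line) - 1), 0.02)
  th <- seq(0, pi, length.out = 3000)
  arc <- make_traj(50 * cos(th), 50 * sin(th))
  expect_lt(abs(spatial_complexity(arc) - 1), 0.02)
  expect_error(spatial_complexity(make_traj(rep(0, 10), rep(0, 10))), "zero-length")
})

test_that("divider and box-count estimators agree on a Koch curve", {
  k <- koch_curve(5)
  tr <- make_traj(k[, 1], k[, 2])
  dv <- spatial_complexity(tr)
  bc <- boxcount_dimension(k, (100 / 3^5) * 3^(0:3))
  analytic <- log(4) / log(3)
  expect_lt(abs(dv - analytic), 0.1)
  expect_lt(abs(bc - analytic), 0.1)
  expect_lt(abs(dv - bc), 0.1)
})

test_that("a dense isotropic walk is rough under both estimators", {
  tr <- random_walk_traj()
  dv <- spatial_complexity(tr)
  expect_gt(dv, 1.3)
  bc <- boxcount_dimension(cbind(tr$x_mm, tr$y_mm), 1.6 * 2^(0:3))
  expect_gt(bc, 1.3)
})

test_that("temporal scaling spans its analytic anchors", {
  still <- make_traj(rep(0, 5000), rep(0, 5000))
  expect_equal(temporal_scaling(still), 0)  # no events, by convention
  # an event in every 0.5-s bin
  expect_lt(abs(temporal_boxcount_exponent(seq(0.25, 1199.75, by = 0.5)) - 1), 0.02)
  # Cantor set of event times: dimension log2 / log3
  expect_lt(abs(temporal_boxcount_exponent(cantor_times(8)) - log(2) / log(3)), 0.05)
})

test_that("frame-loss adjustment rescales only extensive measures", {
  f <- data.frame(immobility_duration = 2, microevents = 820,
                  displacement = 1.5, area = 30, spatial_complexity = 1.4,
                  temporal_scaling = 0.5, loss_fraction = 0.18)
  class(f) <- c("motion_feature_set", "data.frame")
  adj <- adjust_for_loss(f, 0.18)
  expect_equal(adj$microevents, 1000)
  expect_equal(adj$displacement, 1.5 / 0.82)
  expect_equal(adj$area, 30)
  expect_equal(adj$spatial_complexity, 1.4)
  expect_identical(adjust_for_loss(f, 0)$microevents, 820)
  expect_warning(adjust_for_loss(f, 0.6), "50%")
  expect_error(adjust_for_loss(f, 1), "loss_fraction")
})

test_that("masked-then-adjusted displacement matches the unmasked value", {
  mp <- movement_model_params(session_duration = 300)
  tr <- simulate_trajectory(mp, seed = 19)
  ref <- motion_features(tr)
  lost <- inject_frame_loss(tr, 0.18, seed = 20)
  adj <- motion_features(lost)
  expect_lt(abs(adj$displacement / ref$displacement - 1), 0.1)
  expect_lt(abs(adj$microevents / ref$microevents - 1), 0.15)
})

test_that("all measures are rigid-motion invariant and scale-covariant", {
  tr <- random_walk_traj(4000, step = 0.7, seed = 41)
  a <- pi / 7
  rot <- make_traj(10 + tr$x_mm * cos(a) - tr$y_mm * sin(a),
                   -5 + tr$x_mm * sin(a) + tr$y_mm * cos(a))
  for (f in list(count_microevents, total_displacement, movement_area,
                 immobility_statistics, spatial_complexity, temporal_scaling))
    expect_equal(f(rot), f(tr), tolerance = 1e-8)
  dbl <- make_traj(2 * tr$x_mm, 2 * tr$y_mm)
  expect_equal(total_displacement(dbl), 2 * total_displacement(tr))
  expect_equal(movement_area(dbl), 4 * movement_area(tr))
  expect_lt(abs(spatial_complexity(dbl) - spatial_complexity(tr)), 0.02)
  expect_lt(abs(temporal_scaling(dbl) - temporal_scaling(tr)), 0.02)
})

test_that("extracted features track the generator parameters", {
  rates <- c(2, 5, 10, 20, 40)
  roughs <- c(0.05, 0.15, 0.25, 0.4, 0.6)
  micro <- ts <- sc <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    mp <- movement_model_params(bout_rate = rates[i], path_roughness = roughs[j],
                                session_duration = 120)
    f <- suppressWarnings(motion_features(
      simulate_trajectory(mp, seed = 300 + 10 * i + j)))
    micro[i, j] <- f$microevents; ts[i, j] <- f$temporal_scaling
    sc[i, j] <- f$spatial_complexity
  }
  expect_gt(cor(rates, rowMeans(micro), method = "spearman"), 0.9)
  expect_gt(cor(rates, rowMeans(ts), method = "spearman"), 0.9)
  expect_gt(cor(roughs, colMeans(sc), method = "spearman"), 0.9)
})
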