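test_that("frame means collapse movies correctly", {
  p <- make_stimulus_protocol(10, 2, onset_s = 1)
  # constant movie
  frames <- array(7, dim = c(5, 4, 4))
  mv <- structure(list(frames = frames, frame_rate_hz = 10,
                       pixel_size_um = 1, region_label = "GPe",
                       protocol = p), class = "ffn_movie")
  expect_equal(frame_mean_trace(mv)$values, rep(7, 5))
  # 2x2 frame with rows 0 and 10
  frames2 <- array(0, dim = c(1, 2, 2))
  frames2[1, 2, ] <- 10
  mv2 <- structure(list(frames = frames2, frame_rate_hz = 10,
                        pixel_size_um = 1, region_label = "GPe",
                        protocol = p), class = "ffn_movie")
  expect_equal(frame_mean_trace(mv2)$values, 5)
  # seeded movie against a brute-force double loop
  set.seed(21)
  frames3 <- array(runif(6 * 3 * 4), dim = c(6, 3, 4))
  mv3 <- structure(list(frames = frames3, frame_rate_hz = 10,
                        pixel_size_um = 1, region_label = "GPe",
                        protocol = p), class = "ffn_movie")
  got <- frame_mean_trace(mv3)$values
  for (t in 1:6) {
    acc <- 0
    for (i in 1:3) for (j in 1:4) acc <- acc + frames3[t, i, j]
    expect_equal(got[t], acc / 12, tolerance = 1e-12)
  }
})

test_that("baseline fitting is exact on constant and linear input", {
  p <- make_stimulus_protocol(10, 5, onset_s = 1)
  t <- seq(0, 2.9, by = 0.1)
  b1 <- fit_baseline(raw_trace(t, rep(100, length(t)), 10), p)
  expect_equal(b1$slope, 0, tolerance = 1e-10)
  expect_equal(b1$intercept, 100, tolerance = 1e-10)
  b2 <- fit_baseline(raw_trace(t, 100 - 2 * t, 10), p)
  expect_equal(b2$slope, -2, tolerance = 1e-10)
  expect_equal(b2$intercept, 100, tolerance = 1e-10)
  expect_equal(b2$fit_window_s, c(0.5, 1))
})

test_that("baseline coefficients match the normal-equations oracle", {
  p <- make_stimulus_protocol(10, 5, onset_s = 1)
  set.seed(31)
  t <- seq(0, 2.9, by = 0.1)
  v <- 100 - 1.5 * t + rnorm(length(t), 0, 2)
  b <- fit_baseline(raw_trace(t, v, 10), p)
  idx <- which(t >= 0.5 & t < 1 - 1e-9)
  X <- cbind(1, t[idx])
  beta <- solve(t(X) %*% X, t(X) %*% v[idx])
  expect_equal(b$intercept, beta[1], tolerance = 1e-9)
  expect_equal(b$slope, beta[2], tolerance = 1e-9)
})

test_that("baseline fitting requires enough pre-stimulus samples", {
  p <- make_stimulus_protocol(10, 5, onset_s = 0.05)
  t <- seq(0, 2, by = 0.1)
  expect_error(fit_baseline(raw_trace(t, t * 0 + 1, 10), p),
               "pre-stimulus")
})

test_that("dF/F algebra holds: zero, step and bleach-proportional input", {
  p <- make_stimulus_protocol(10, 5, onset_s = 1)
  t <- seq(0, 2.9, by = 0.1)
  # raw identical to its fitted baseline -> all zeros
  raw0 <- raw_trace(t, 100 - 2 * t, 10)
  d0 <- extract_dff(raw0, p)
  expect_equal(d0$values, rep(0, length(t)), tolerance = 1e-9)
  # flat baseline 100, one frame at 110 -> 10 percent
  v <- rep(100, length(t)); v[25] <- 110
  d1 <- extract_dff(raw_trace(t, v, 10), p)
  expect_equal(d1$values[25], 10, tolerance = 1e-9)
  # raw = 1.05 * B(t) with B given: constant 5 percent (bleach cancels)
  b <- structure(list(intercept = 100, slope = -2,
                      fit_window_s = c(0.5, 1)),
                 class = "baseline_model")
  d2 <- compute_dff(raw_trace(t, 1.05 * (100 - 2 * t), 10), b, p)
  expect_equal(d2$values, rep(5, length(t)), tolerance = 1e-9)
})

test_that("a degenerate (non-positive) baseline is refused", {
  p <- make_stimulus_protocol(10, 5, onset_s = 1)
  t <- seq(0, 5.9, by = 0.1)
  raw <- raw_trace(t, pmax(20 - 21 * t, 0.5), 10)
  expect_error(extract_dff(raw, p), "non-positive")
})

test_that("dF/F is invariant to rescaling the raw trace", {
  k <- region_kinetics("GPe")
  p <- make_stimulus_protocol(10, 10, onset_s = 1)
  sim <- simulate_trace(k, p, duration_s = 5, noise_sd = 0.3, seed = 8)
  d1 <- extract_dff(sim$raw, p)
  scaled <- raw_trace(sim$raw$times_s, sim$raw$values * 37.5, 10)
  d2 <- extract_dff(scaled, p)
  expect_equal(d1$values, d2$values, tolerance = 1e-9)
})

test_that("baseline correction nulls a noiseless bleaching trace", {
  k <- region_kinetics(amplitude_per_pulse = 0, bleach_slope = 0.01)
  p <- make_stimulus_protocol(10, 10, onset_s = 1)
  sim <- simulate_trace(k, p, duration_s = 8, noise_sd = 0)
  d <- extract_dff(sim$raw, p)
  expect_lt(abs(mean(d$values)), 1e-9)
})

test_that("trapezoidal AUC reproduces the analytic examples", {
  # triangle 0 -> 10 -> 0 at 0.1 s spacing: 1.0 percent*s
  d <- make_dff(c(0, 10, 0, 0), t0 = 0)
  expect_identical(auc(d, c(0, 0.2)), 1.0)
  # zero trace
  expect_equal(auc(make_dff(rep(0, 20)), c(0, 1)), 0)
  # constant 10 over a 1 s window at 10 Hz
  expect_equal(auc(make_dff(rep(10, 20)), c(0, 1)), 10.0)
  # frame-index abscissa: same triangle integrates to 10 frames
  expect_equal(auc(make_dff(c(0, 10, 0, 0), t0 = 0), c(0, 0.2),
                   abscissa = "frames"), 10.0)
})

test_that("AUC is additive over adjacent half-open windows", {
  set.seed(41)
  for (rep in 1:10) {
    v <- rnorm(60)
    d <- make_dff(v, t0 = 0)
    lo <- 0.3; mid <- round(runif(1, 0.8, 3), 1); hi <- 5
    expect_equal(auc(d, c(lo, mid)) + auc(d, c(mid, hi)),
                 auc(d, c(lo, hi)), tolerance = 1e-12)
  }
})

test_that("AUC windows outside the trace are rejected", {
  d <- make_dff(rep(1, 10), t0 = 0)
  expect_error(auc(d, c(0.5, 2)), "outside")
  expect_error(auc(d, c(-1, 0.5)), "outside")
  expect_error(auc(d, c(0.5, 0.5)), "start < end")
})

test_that("transient averaging computes pointwise mean and SEM", {
  p <- make_stimulus_protocol(10, 5, onset_s = 1)
  tr <- function(v) make_dff(rep(v, 20), protocol = p)
  # identical traces: SEM 0
  m1 <- average_transients(list(tr(3), tr(3), tr(3)))
  expect_equal(m1$mean, rep(3, 20))
  expect_equal(m1$sem, rep(0, 20))
  expect_equal(m1$n, 3)
  # constants 0 and 10: mean 5, SEM 5 (sd = 7.0711)
  m2 <- average_transients(list(tr(0), tr(10)))
  expect_equal(m2$mean, rep(5, 20))
  expect_equal(m2$sem, rep(5, 20), tolerance = 1e-12)
  # seeded random set against a brute-force loop
  set.seed(51)
  vals <- replicate(4, rnorm(20), simplify = FALSE)
  m3 <- average_transients(lapply(vals, make_dff, protocol = p))
  for (i in 1:20) {
    xi <- vapply(vals, `[`, numeric(1), i)
    expect_equal(m3$mean[i], mean(xi), tolerance = 1e-12)
    expect_equal(m3$sem[i], sd(xi) / 2, tolerance = 1e-12)
  }
})

test_that("averaging refuses mismatched time bases", {
  a <- make_dff(rep(1, 10), t0 = 0)
  b <- make_dff(rep(1, 10), t0 = 0.05)
  expect_error(average_transients(list(a, b)), "time base")
})
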