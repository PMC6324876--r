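test_that("zero evoked amplitude and zero noise give the bare bleaching baseline", {
  k <- region_kinetics(amplitude_per_pulse = 0, bleach_slope = 0.01)
  p <- make_stimulus_protocol(10, 10, onset_s = 1)
  sim <- simulate_trace(k, p, duration_s = 5, noise_sd = 0)
  expect_equal(sim$raw$values,
               100 * (1 - 0.01 * sim$raw$times_s), tolerance = 1e-12)
})

test_that("a single pulse with near-instant rise reproduces its amplitude as peak dF/F", {
  # sampled fast enough to land a frame on the kernel peak
  k <- region_kinetics(amplitude_per_pulse = 10, rise_tau_s = 1e-5,
                       decay_tau_s = 1, bleach_slope = 0)
  p <- make_stimulus_protocol(10, 1, onset_s = 1)
  sim <- simulate_trace(k, p, calcium_mM = 2.4, duration_s = 5,
                        frame_rate_hz = 1000, noise_sd = 0)
  d <- extract_dff(sim$raw, p)
  expect_equal(max(d$values), sim$truth$amplitudes[1], tolerance = 2e-3)
})

test_that("calcium scales amplitudes by the Hill ratio", {
  k <- region_kinetics(amplitude_per_pulse = 5)
  p <- make_stimulus_protocol(10, 3, onset_s = 1)
  a_05 <- simulate_trace(k, p, calcium_mM = 0.5,
                         duration_s = 4)$truth$amplitudes
  a_2 <- simulate_trace(k, p, calcium_mM = 2,
                        duration_s = 4)$truth$amplitudes
  hill <- function(c, ec50 = 1, h = 2) c^h / (c^h + ec50^h)
  expect_equal(a_05 / a_2, rep(hill(0.5) / hill(2), 3), tolerance = 1e-12)
  # closed form of the Hill curve itself
  expect_equal(hill_activation(c(0.5, 2, 4)),
               c(0.2, 0.8, 16 / 17), tolerance = 1e-12)
})

test_that("expected amplitude is non-decreasing in calcium and saturates", {
  k <- region_kinetics(amplitude_per_pulse = 5)
  p <- make_stimulus_protocol(10, 1, onset_s = 1)
  ca <- c(0, 0.25, 0.5, 1, 2, 4, 8)
  amps <- vapply(ca, function(cc) {
    simulate_trace(k, p, calcium_mM = cc, duration_s = 3)$truth$amplitudes
  }, numeric(1))
  expect_true(all(diff(amps) >= 0))
  # saturation above 2 mM: the 2 -> 4 increment is smaller than 0.5 -> 2
  expect_lt(hill_activation(4) - hill_activation(2),
            hill_activation(2) - hill_activation(0.5))
})

test_that("identical seeds give bit-identical traces", {
  k <- region_kinetics("GPe")
  p <- make_stimulus_protocol(10, 10, onset_s = 1)
  s1 <- simulate_trace(k, p, duration_s = 5, noise_sd = 1, seed = 11)
  s2 <- simulate_trace(k, p, duration_s = 5, noise_sd = 1, seed = 11)
  s3 <- simulate_trace(k, p, duration_s = 5, noise_sd = 1, seed = 12)
  expect_identical(s1$raw$values, s2$raw$values)
  expect_false(identical(s1$raw$values, s3$raw$values))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_trace(region_kinetics("GPe"),
                           make_stimulus_protocol(10, 5, onset_s = 1),
                           duration_s = 4, noise_sd = 1, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("inter-train recovery scales amplitudes as 1 - exp(-gap/tau)", {
  k <- region_kinetics("striatum")  # recovery_tau 60 s
  p <- make_stimulus_protocol(10, 2, onset_s = 1)
  full <- simulate_trace(k, p, duration_s = 4)$truth$amplitudes
  part <- simulate_trace(k, p, duration_s = 4,
                         prev_train_gap_s = 10)$truth$amplitudes
  expect_equal(part / full, rep(1 - exp(-10 / 60), 2), tolerance = 1e-12)
  # the GPe preset recovers much faster at the same gap
  kg <- region_kinetics("GPe")
  pg <- simulate_trace(kg, p, duration_s = 4,
                       prev_train_gap_s = 10)$truth$amplitudes
  fg <- simulate_trace(kg, p, duration_s = 4)$truth$amplitudes
  expect_equal(unique(round(pg / fg, 12)), 1 - exp(-1))
})

test_that("facilitation with infinite timescale reduces to the linear ramp", {
  k <- region_kinetics(amplitude_per_pulse = 1,
                       facilitation_per_pulse = 0.5,
                       facilitation_tau_s = Inf)
  p <- make_stimulus_protocol(10, 4, onset_s = 1)
  amps <- simulate_trace(k, p, calcium_mM = 1e6,
                         duration_s = 4)$truth$amplitudes
  expect_equal(amps, 1 + 0.5 * (0:3), tolerance = 1e-5)
})

test_that("protocols extending past the recording are rejected", {
  k <- region_kinetics("GPe")
  p <- make_stimulus_protocol(1, 10, onset_s = 1)  # last pulse at 10 s
  expect_error(simulate_trace(k, p, duration_s = 5), "beyond")
})

test_that("region presets differ in the documented directions", {
  ks <- region_kinetics("striatum")
  kg <- region_kinetics("GPe")
  expect_gt(ks$decay_tau_s, kg$decay_tau_s)
  expect_gt(ks$recovery_tau_s, kg$recovery_tau_s)
  expect_equal(ks$facilitation_per_pulse, 0)
  expect_gt(kg$facilitation_per_pulse, 0)
})
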