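# Shared fixture builders. Everything is generated in code; the only
# stored fixture is the frozen reference Canny mask (plain text).

# Deterministic synthetic baseline image: flat background of 10 plus four
# Gaussian puncta. The frozen reference mask in fixtures/ was computed
# from exactly this image.
make_canny_fixture_image <- function() {
  img <- matrix(10, 48, 48)
  ps <- list(c(12, 10, 40, 1.5), c(30, 25, 60, 2.0),
             c(20, 38, 50, 1.2), c(38, 12, 35, 1.8))
  for (p in ps) {
    img <- img + p[3] * ffnquant:::punctum_profile(48, 48, p[1], p[2], p[4])
  }
  img
}

read_reference_mask <- function() {
  as.matrix(utils::read.table(
    test_path("fixtures", "canny_reference_mask_synthetic.txt"),
    comment.char = "#"))
}

# Build a dff_trace directly from values (bypassing baseline machinery)
# for analytic tests.
make_dff <- function(values, frame_rate_hz = 10, protocol = NULL,
                     t0 = 0) {
  if (is.null(protocol)) {
    protocol <- make_stimulus_protocol(10, 10, onset_s = 1)
  }
  times <- t0 + (seq_along(values) - 1) / frame_rate_hz
  structure(list(times_s = times, values = as.numeric(values),
                 frame_rate_hz = frame_rate_hz, protocol = protocol),
            class = "dff_trace")
}

# Noiseless exponential transient as a dff_trace: A * exp(-(t-onset)/tau)
# for t >= onset, 0 before.
make_exp_dff <- function(tau, amplitude = 10, onset_s = 1,
                         duration_s = 8, frame_rate_hz = 10,
                         noise_sd = 0, seed = NULL) {
  protocol <- make_stimulus_protocol(10, 1, onset_s = onset_s)
  times <- seq(0, duration_s - 1 / frame_rate_hz, by = 1 / frame_rate_hz)
  v <- ifelse(times >= onset_s,
              amplitude * exp(-(times - onset_s) / tau), 0)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v + stats::rnorm(length(v), 0, noise_sd)
  }
  structure(list(times_s = times, values = v,
                 frame_rate_hz = frame_rate_hz, protocol = protocol),
            class = "dff_trace")
}

# A tiny deterministic session with explicit positions and AUCs.
make_session <- function(x, y, auc, extent_um = c(1000, 600)) {
  structure(list(
    slice_id = "s1", region = "GPe", extent_um = extent_um,
    fovs = data.frame(
      fov_id = sprintf("fov%03d", seq_along(x)),
      x_um = x, y_um = y, auc = auc,
      canny_sum = 0L, initial_f = 100, is_hotspot = FALSE,
      stringsAsFactors = FALSE)),
    class = "slice_session")
}
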