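# Generative model for single-field fluorescence time courses.

# Difference-of-exponentials kernel normalized to unit peak; h(t) = 0 for
# t < 0. Peak time t* = log(decay/rise) / (1/rise - 1/decay).
transient_kernel <- function(t, rise_tau_s, decay_tau_s) {
  tstar <- log(decay_tau_s / rise_tau_s) /
    (1 / rise_tau_s - 1 / decay_tau_s)
  peak <- exp(-tstar / decay_tau_s) - exp(-tstar / rise_tau_s)
  h <- ifelse(t >= 0,
              (exp(-t / decay_tau_s) - exp(-t / rise_tau_s)) / peak,
              0)
  pmax(h, 0)
}

# Per-pulse amplitudes in percent dF/F: Hill calcium scaling, facilitation
# accumulated from preceding pulses with exponential forgetting, and an
# optional inter-train recovery factor.
pulse_amplitudes <- function(kinetics, protocol, calcium_mM,
                             recovery_scale = 1) {
  tp <- protocol$pulse_times_s
  n <- length(tp)
  facil <- numeric(n)
  for (p in seq_len(n)) {
    if (p > 1L) {
      dt <- tp[p] - tp[seq_len(p - 1L)]
      facil[p] <- sum(exp(-dt / kinetics$facilitation_tau_s))
    }
  }
  kinetics$amplitude_per_pulse *
    hill_activation(calcium_mM, kinetics$ca_ec50_mM, kinetics$ca_hill) *
    (1 + kinetics$facilitation_per_pulse * facil) *
    recovery_scale
}

#' Simulate a whole-field fluorescence trace with known ground truth
#'
#' Generates the frame-mean fluorescence time course of one field of view
#' under a stimulus train:
#' \deqn{F(t) = F_0 (1 - b t) + \frac{F_0}{100} \sum_p A_p h(t - t_p)
#'       + \epsilon(t)}
#' with linear photobleaching slope `b`, per-pulse amplitudes `A_p`
#' (percent dF/F; see [region_kinetics()]), a difference-of-exponentials
#' kernel `h` normalized to unit peak, and i.i.d. Gaussian noise of
#' standard deviation `noise_sd` (intensity units). An exponential
#' bleaching mode (`F_0 exp(-b t)`) is available.
#'
#' If `prev_train_gap_s` is given, the train is treated as following an
#' earlier identical train by that many seconds and all amplitudes are
#' scaled by the recovery fraction `1 - exp(-gap / recovery_tau_s)`.
#'
#' @param kinetics A [region_kinetics()] object.
#' @param protocol A [make_stimulus_protocol()] object; must end before
#'   `duration_s`.
#' @param calcium_mM Extracellular calcium (mM), >= 0. Default 2.4, a
#'   standard slice perfusate concentration.
#' @param duration_s Recording length (s).
#' @param frame_rate_hz Sampling rate (Hz).
#' @param noise_sd Gaussian noise SD in intensity units (0 = noiseless).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @param prev_train_gap_s Optional gap (s) since a previous train.
#' @param bleach_model `"linear"` (default) or `"exponential"`.
#' @return A list with components `raw` (a [raw_trace()]) and `truth`
#'   (class `"ffn_ground_truth"`: per-pulse `amplitudes` in percent dF/F,
#'   `decay_tau_s`, `noise_sd`, `seed`).
#' @examples
#' k <- region_kinetics("GPe")
#' p <- make_stimulus_protocol(10, 10, onset_s = 1)
#' sim <- simulate_trace(k, p, duration_s = 8, noise_sd = 0)
#' sim$truth$amplitudes
#' @export
simulate_trace <- function(kinetics, protocol, calcium_mM = 2.4,
                           duration_s = 8, frame_rate_hz = 10,
                           noise_sd = 0, seed = NULL,
                           prev_train_gap_s = NULL,
                           bleach_model = c("linear", "exponential")) {
  stopifnot(inherits(kinetics, "region_kinetics"),
            inherits(protocol, "stimulus_protocol"))
  bleach_model <- match.arg(bleach_model)
  check_scalar(calcium_mM, "calcium_mM", lower = 0)
  check_scalar(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  check_scalar(frame_rate_hz, "frame_rate_hz", lower = 0,
               strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  last_pulse <- protocol$pulse_times_s[protocol$n_pulses]
  if (last_pulse >= duration_s) {
    stop_invalid("stimulus protocol extends beyond `duration_s`")
  }
  recovery_scale <- 1
  if (!is.null(prev_train_gap_s)) {
    check_scalar(prev_train_gap_s, "prev_train_gap_s", lower = 0)
    recovery_scale <- 1 - exp(-prev_train_gap_s / kinetics$recovery_tau_s)
  }
  amps <- pulse_amplitudes(kinetics, protocol, calcium_mM, recovery_scale)

  n_frames <- floor(duration_s * frame_rate_hz)
  times <- (seq_len(n_frames) - 1) / frame_rate_hz
  f0 <- kinetics$baseline_f0
  base <- switch(bleach_model,
    linear = f0 * (1 - kinetics$bleach_slope * times),
    exponential = f0 * exp(-kinetics$bleach_slope * times))
  evoked <- numeric(n_frames)
  for (p in seq_along(amps)) {
    evoked <- evoked + amps[p] * transient_kernel(
      times - protocol$pulse_times_s[p],
      kinetics$rise_tau_s, kinetics$decay_tau_s)
  }
  values <- base + f0 * evoked / 100
  if (noise_sd > 0) {
    values <- values + with_seed(seed, stats::rnorm(n_frames, 0, noise_sd))
  }
  truth <- structure(
    list(amplitudes = amps, decay_tau_s = kinetics$decay_tau_s,
         noise_sd = noise_sd, seed = seed),
    class = "ffn_ground_truth")
  list(raw = raw_trace(times, values, frame_rate_hz), truth = truth)
}
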