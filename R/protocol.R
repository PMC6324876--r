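#' Construct an electrical stimulus protocol
#'
#' A stimulus protocol describes a single train of electrical pulses
#' delivered to a brain slice: `n_pulses` pulses at `frequency_hz`, the
#' first at `onset_s`. Pulse times are `onset_s + k / frequency_hz` for
#' `k = 0, ..., n_pulses - 1`. Pulse width and current default to the
#' 600 us x 200 uA pulses typical of slice stimulation through a bipolar
#' electrode; they are metadata and do not affect simulation or analysis.
#'
#' @param frequency_hz Pulse frequency within the train (Hz), > 0.
#' @param n_pulses Number of pulses, >= 1.
#' @param onset_s Time of the first pulse (s), relative to recording start.
#' @param pulse_width_us Pulse width (microseconds), metadata.
#' @param current_uA Stimulation current (microamps), metadata.
#'
#' @return An object of class `"stimulus_protocol"`: a list with fields
#'   `onset_s`, `pulse_times_s`, `frequency_hz`, `n_pulses`,
#'   `pulse_width_us`, `current_uA`.
#' @examples
#' p <- make_stimulus_protocol(10, 10, onset_s = 1)
#' p$pulse_times_s  # 1.0, 1.1, ..., 1.9
#' @export
make_stimulus_protocol <- function(frequency_hz, n_pulses, onset_s = 1,
                                   pulse_width_us = 600, current_uA = 200) {
  check_scalar(frequency_hz, "frequency_hz", lower = 0, strict_lower = TRUE)
  if (!is_scalar_number(n_pulses) || n_pulses < 1 ||
      n_pulses != round(n_pulses)) {
    stop_invalid("`n_pulses` must be a positive integer")
  }
  check_scalar(onset_s, "onset_s", lower = 0)
  n_pulses <- as.integer(n_pulses)
  structure(
    list(
      onset_s = onset_s,
      pulse_times_s = onset_s + (seq_len(n_pulses) - 1) / frequency_hz,
      frequency_hz = frequency_hz,
      n_pulses = n_pulses,
      pulse_width_us = pulse_width_us,
      current_uA = current_uA
    ),
    class = "stimulus_protocol"
  )
}

#' Stimulus window of a protocol
#'
#' The default analysis window for AUC scoring: `[onset, onset +
#' n_pulses / frequency_hz]`, i.e. the nominal duration of the stimulus
#' period (a 10-pulse 10 Hz train occupies 1 s).
#'
#' @param protocol A `stimulus_protocol`.
#' @return Numeric length-2 vector `c(start_s, end_s)`.
#' @export
stimulus_window <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  c(protocol$onset_s,
    protocol$onset_s + protocol$n_pulses / protocol$frequency_hz)
}

# Span from first to last pulse, (n - 1) / f.
train_span_s <- function(protocol) {
  (protocol$n_pulses - 1) / protocol$frequency_hz
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf(
    "Stimulus protocol: %d pulse(s) at %g Hz, onset %g s (%g us x %g uA)\n",
    x$n_pulses, x$frequency_hz, x$onset_s, x$pulse_width_us, x$current_uA))
  invisible(x)
}
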