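# Pulse-resolved derivative analysis and decay kinetics.

#' Frame-binned derivative of a dF/F trace
#'
#' First difference of the percent dF/F signal per frame interval (100 ms
#' bins at 10 Hz imaging). Each bin spans `[t_i, t_{i+1})` and is indexed
#' by its start time, so the bin "after" a pulse is the one whose start
#' coincides with (or contains) the pulse time; at stimulation rates
#' faster than the frame rate several pulses share one bin. The
#' cumulative sum of the derivative reconstructs the trace up to its
#' first value exactly.
#'
#' @param dff A [compute_dff()] trace with at least 2 samples.
#' @param protocol Optional protocol (defaults to the trace's own);
#'   carried on the result.
#' @return Object of class `"derivative_trace"`: `bin_times_s` (bin start
#'   times, length `n - 1`), `values` (percent dF/F per bin),
#'   `frame_rate_hz`, `protocol`.
#' @export
pulse_binned_derivative <- function(dff, protocol = NULL) {
  stopifnot(inherits(dff, "dff_trace"))
  if (is.null(protocol)) protocol <- dff$protocol
  n <- length(dff$values)
  if (n < 2L) stop_invalid("need at least 2 samples for a derivative")
  structure(list(bin_times_s = dff$times_s[-n],
                 values = diff(dff$values),
                 frame_rate_hz = dff$frame_rate_hz,
                 protocol = protocol),
            class = "derivative_trace")
}

# Bin index (1..n-1) containing time `x`: bins are [t_i, t_{i+1}).
derivative_bin_index <- function(deriv, x) {
  t0 <- deriv$bin_times_s
  dt <- 1 / deriv$frame_rate_hz
  i <- findInterval(x + 1e-9, t0)
  if (i < 1L || i > length(t0) || x >= t0[length(t0)] + dt) {
    stop_invalid(sprintf("time %g s falls outside the derivative bins", x))
  }
  i
}

#' Derivative at the pre-stimulus, first-pulse and second-pulse landmarks
#'
#' Returns the frame-binned derivative in three 100-ms landmark bins: the
#' bin immediately before stimulation, the bin following the first pulse,
#' and the bin following the second pulse. These landmarks quantify how
#' much of the transient is contributed by the first electrical pulse.
#'
#' @param dff A [compute_dff()] trace.
#' @param protocol A protocol with at least 2 pulses (defaults to the
#'   trace's own).
#' @return Named numeric vector `c(pre, pulse1, pulse2)`, percent dF/F
#'   per bin.
#' @export
derivative_at_landmarks <- function(dff, protocol = NULL) {
  stopifnot(inherits(dff, "dff_trace"))
  if (is.null(protocol)) protocol <- dff$protocol
  if (protocol$n_pulses < 2L) {
    stop_invalid("landmark analysis needs a protocol with >= 2 pulses")
  }
  deriv <- pulse_binned_derivative(dff, protocol)
  dt <- 1 / deriv$frame_rate_hz
  c(pre = deriv$values[derivative_bin_index(deriv, protocol$onset_s - dt)],
    pulse1 = deriv$values[derivative_bin_index(
      deriv, protocol$pulse_times_s[1])],
    pulse2 = deriv$values[derivative_bin_index(
      deriv, protocol$pulse_times_s[2])])
}

#' Decay time and goodness of fit of a transient
#'
#' Finds the post-stimulus peak of the percent dF/F trace (the maximum
#' between stimulus onset and the end of the train plus 0.5 s; ties are
#' broken by the earliest frame), fits a line to the log-transformed
#' values over the post-peak samples that remain above
#' `floor_fraction * peak` (a contiguous run starting at the peak;
#' non-positive samples are thereby excluded rather than offset), and
#' reports the time for the fitted exponential to fall from the peak to
#' `floor_fraction` of it: `decay_time = -log(1 / floor_fraction) /
#' log_slope`. For a clean exponential with time constant `tau` and the
#' default `floor_fraction = 0.10`, the decay time is `tau * log(10)`.
#' The decay time depends only on the shape of the trace, not on its
#' amplitude.
#'
#' @param dff A [compute_dff()] trace.
#' @param protocol Optional protocol (defaults to the trace's own).
#' @param floor_fraction Fraction of the peak defining the decay endpoint
#'   and the fit floor; 0.10 by default, 0.5 gives the half-decay time.
#' @return Object of class `"decay_result"`: `decay_time_s`, `log_slope`
#'   (1/s), `r_squared`, `fit_window_s`, `peak`, `peak_time_s`,
#'   `n_fit_samples`.
#' @export
decay_metrics <- function(dff, protocol = NULL, floor_fraction = 0.10) {
  stopifnot(inherits(dff, "dff_trace"))
  if (is.null(protocol)) protocol <- dff$protocol
  check_scalar(floor_fraction, "floor_fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  t <- dff$times_s
  v <- dff$values
  tol <- 1e-9
  win_end <- protocol$onset_s +
    protocol$n_pulses / protocol$frequency_hz + 0.5
  in_win <- which(t >= protocol$onset_s - tol & t <= win_end + tol)
  if (length(in_win) == 0L) stop_invalid("no samples in the peak window")
  peak_idx <- in_win[which.max(v[in_win])]  # which.max takes earliest tie
  peak <- v[peak_idx]
  if (peak <= 0) stop_invalid("non-positive post-stimulus peak")

  floor_val <- floor_fraction * peak
  post <- seq(peak_idx, length(v))
  below <- which(v[post] <= floor_val)
  fit_idx <- if (length(below) == 0L) post else post[seq_len(below[1] - 1L)]
  if (length(fit_idx) < 3L) {
    stop_invalid("fewer than 3 samples above the decay floor; ",
                 "cannot fit the decay")
  }
  tf <- t[fit_idx]
  lf <- log(v[fit_idx])
  fit <- stats::lm.fit(cbind(1, tf), lf)
  slope <- unname(fit$coefficients[2])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((lf - mean(lf))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  decay_time <- if (slope < 0) -log(1 / floor_fraction) / slope else NA_real_
  structure(list(decay_time_s = decay_time, log_slope = slope,
                 r_squared = r2,
                 fit_window_s = c(tf[1], tf[length(tf)]),
                 peak = peak, peak_time_s = t[peak_idx],
                 n_fit_samples = length(fit_idx)),
            class = "decay_result")
}

#' @export
print.decay_result <- function(x, ...) {
  cat(sprintf(
    "Decay: time to floor %.4g s (log slope %.4g /s, R^2 %.4f, n = %d)\n",
    x$decay_time_s, x$log_slope, x$r_squared, x$n_fit_samples))
  invisible(x)
}
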