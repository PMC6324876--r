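# Baseline-corrected percent dF/F extraction and AUC scoring.

#' Raw fluorescence trace
#'
#' A uniformly sampled whole-field fluorescence time course (the mean of
#' all pixels in each frame, in arbitrary intensity units).
#'
#' @param times_s Sample times (s), uniformly spaced at `1 / frame_rate_hz`.
#' @param values Mean fluorescence per frame.
#' @param frame_rate_hz Sampling rate (Hz).
#' @return Object of class `"raw_trace"`.
#' @export
raw_trace <- function(times_s, values, frame_rate_hz) {
  if (length(times_s) != length(values) || length(values) < 1L) {
    stop_invalid("`times_s` and `values` must have equal positive length")
  }
  check_scalar(frame_rate_hz, "frame_rate_hz", lower = 0,
               strict_lower = TRUE)
  if (length(times_s) > 1L) {
    dt <- diff(times_s)
    if (any(abs(dt - 1 / frame_rate_hz) > 1e-6 / frame_rate_hz)) {
      stop_invalid("`times_s` must be uniformly spaced at 1/frame_rate_hz")
    }
  }
  structure(list(times_s = as.numeric(times_s),
                 values = as.numeric(values),
                 frame_rate_hz = frame_rate_hz),
            class = "raw_trace")
}

#' Frame-mean trace of a movie
#'
#' Collapses a T x H x W movie to one value per frame, the arithmetic mean
#' of all pixels — the whole-field measurement used in sparsely innervated
#' regions where individual puncta cannot be tracked.
#'
#' @param movie An [simulate_movie()] / [read_movie()] movie.
#' @return A [raw_trace()].
#' @export
frame_mean_trace <- function(movie) {
  stopifnot(inherits(movie, "ffn_movie"))
  d <- dim(movie$frames)
  if (is.null(d) || length(d) != 3L || any(d == 0L)) {
    stop_invalid("movie has an empty or malformed frame stack")
  }
  m <- movie$frames
  dim(m) <- c(d[1], d[2] * d[3])
  times <- (seq_len(d[1]) - 1) / movie$frame_rate_hz
  raw_trace(times, rowMeans(m), movie$frame_rate_hz)
}

#' Fit the pre-stimulus baseline
#'
#' Ordinary least-squares line fitted to the `window_s` (default 0.5 s) of
#' the trace immediately prior to stimulation. The fitted line, evaluated
#' over the whole recording, is the baseline F used for dF/F; fitting a
#' line (rather than taking a mean) removes slow drift from photobleaching
#' or washout of the dye.
#'
#' @param raw A [raw_trace()].
#' @param protocol A [make_stimulus_protocol()]; the fit window ends at
#'   `protocol$onset_s`.
#' @param window_s Length (s) of the pre-stimulus fit window.
#' @return Object of class `"baseline_model"` with `slope`, `intercept`
#'   and `fit_window_s`.
#' @export
fit_baseline <- function(raw, protocol, window_s = 0.5) {
  stopifnot(inherits(raw, "raw_trace"),
            inherits(protocol, "stimulus_protocol"))
  check_scalar(window_s, "window_s", lower = 0, strict_lower = TRUE)
  onset <- protocol$onset_s
  tol <- 1e-9
  idx <- which(raw$times_s >= onset - window_s - tol &
               raw$times_s < onset - tol)
  if (length(idx) < 2L) {
    stop_invalid(sprintf(
      "need >= 2 pre-stimulus samples in [%g, %g) to fit a baseline",
      onset - window_s, onset))
  }
  t <- raw$times_s[idx]
  v <- raw$values[idx]
  fit <- stats::lm.fit(cbind(1, t), v)
  structure(list(intercept = unname(fit$coefficients[1]),
                 slope = unname(fit$coefficients[2]),
                 fit_window_s = c(onset - window_s, onset)),
            class = "baseline_model")
}

# Evaluate the baseline line at arbitrary times.
predict_baseline <- function(baseline, times_s) {
  baseline$intercept + baseline$slope * times_s
}

#' Convert a raw trace to percent dF/F
#'
#' Subtracts the fitted baseline line B(t), extrapolated over the whole
#' recording, and divides by it:
#' `dff(t) = 100 * (F(t) - B(t)) / B(t)`.
#' Dividing by the per-frame fitted value (not the window mean) cancels a
#' linear bleaching trend exactly.
#'
#' @param raw A [raw_trace()].
#' @param baseline A [fit_baseline()] model.
#' @param protocol The [make_stimulus_protocol()] associated with the
#'   recording (carried on the result for windowing).
#' @return Object of class `"dff_trace"`: `times_s`, `values` (percent),
#'   `frame_rate_hz`, `protocol`.
#' @export
compute_dff <- function(raw, baseline, protocol) {
  stopifnot(inherits(raw, "raw_trace"),
            inherits(baseline, "baseline_model"),
            inherits(protocol, "stimulus_protocol"))
  b <- predict_baseline(baseline, raw$times_s)
  if (any(b <= 0)) {
    stop_invalid("fitted baseline is non-positive over the trace; ",
                 "cannot form dF/F")
  }
  structure(list(times_s = raw$times_s,
                 values = 100 * (raw$values - b) / b,
                 frame_rate_hz = raw$frame_rate_hz,
                 protocol = protocol),
            class = "dff_trace")
}

#' One-step extraction: baseline fit plus dF/F
#'
#' @param raw A [raw_trace()] (or a movie, which is first collapsed with
#'   [frame_mean_trace()]).
#' @inheritParams fit_baseline
#' @return A `"dff_trace"`.
#' @export
extract_dff <- function(raw, protocol, window_s = 0.5) {
  if (inherits(raw, "ffn_movie")) raw <- frame_mean_trace(raw)
  compute_dff(raw, fit_baseline(raw, protocol, window_s), protocol)
}

#' Trapezoidal area under a dF/F trace
#'
#' Composite trapezoid over the half-open window `[start, end)`: every
#' inter-sample segment whose left sample time falls in the window
#' contributes `(v_i + v_{i+1}) / 2 * dt`. The half-open convention makes
#' AUC additive over adjacent windows sharing a sample point. Units are
#' percent dF/F times seconds by default; `abscissa = "frames"` uses the
#' frame index as abscissa instead (dt = 1 frame), the dialect of
#' analyses that integrate "over frames".
#'
#' @param dff A [compute_dff()] trace.
#' @param window_s Length-2 numeric `c(start, end)` in seconds; default is
#'   the protocol's [stimulus_window()].
#' @param abscissa `"seconds"` (default) or `"frames"`.
#' @return Scalar AUC.
#' @examples
#' # triangle 0 -> 10 -> 0 percent sampled at 10 Hz has AUC 1 %*s
#' @export
auc <- function(dff, window_s = NULL,
                abscissa = c("seconds", "frames")) {
  stopifnot(inherits(dff, "dff_trace"))
  abscissa <- match.arg(abscissa)
  if (is.null(window_s)) window_s <- stimulus_window(dff$protocol)
  if (length(window_s) != 2L || !all(is.finite(window_s)) ||
      window_s[1] >= window_s[2]) {
    stop_invalid("`window_s` must be c(start, end) with start < end")
  }
  t <- dff$times_s
  n <- length(t)
  tol <- 1e-9
  if (window_s[1] < t[1] - tol || window_s[2] > t[n] + tol) {
    stop_invalid("AUC window lies outside the trace support")
  }
  left <- which(t >= window_s[1] - tol & t < window_s[2] - tol)
  left <- left[left < n]
  if (length(left) == 0L) return(0)
  v <- dff$values
  dt <- if (abscissa == "seconds") 1 / dff$frame_rate_hz else 1
  sum((v[left] + v[left + 1L]) / 2) * dt
}

#' Average transients across repeated trials
#'
#' Pointwise mean and standard error across dF/F traces sharing a time
#' base and protocol, the "slice-average" transient obtained from several
#' stimulus trains in a field of view.
#'
#' @param traces List of `"dff_trace"` objects on identical time bases.
#' @return Object of class `"mean_trace"`: `times_s`, `mean`, `sem`
#'   (sample SD / sqrt(n)), `n`, `frame_rate_hz`, `protocol`.
#' @export
average_transients <- function(traces) {
  if (!is.list(traces) || length(traces) < 1L ||
      !all(vapply(traces, inherits, logical(1), "dff_trace"))) {
    stop_invalid("`traces` must be a non-empty list of dff_trace objects")
  }
  t0 <- traces[[1]]$times_s
  same <- vapply(traces, function(x) {
    length(x$times_s) == length(t0) && all(abs(x$times_s - t0) < 1e-9)
  }, logical(1))
  if (!all(same)) stop_invalid("traces do not share a common time base")
  vals <- vapply(traces, `[[`, numeric(length(t0)), "values")
  vals <- matrix(vals, nrow = length(t0))
  n <- length(traces)
  mu <- rowMeans(vals)
  sem <- if (n > 1) apply(vals, 1, stats::sd) / sqrt(n) else rep(0, length(t0))
  structure(list(times_s = t0, mean = mu, sem = sem, n = n,
                 frame_rate_hz = traces[[1]]$frame_rate_hz,
                 protocol = traces[[1]]$protocol),
            class = "mean_trace")
}

# A mean_trace can be analysed like a dff_trace (AUC, kinetics): convert.
#' Convert a mean trace back to a dff_trace
#' @param mean_trace A [average_transients()] result.
#' @return A `"dff_trace"` whose values are the pointwise mean.
#' @export
as_dff_trace <- function(mean_trace) {
  stopifnot(inherits(mean_trace, "mean_trace"))
  structure(list(times_s = mean_trace$times_s, values = mean_trace$mean,
                 frame_rate_hz = mean_trace$frame_rate_hz,
                 protocol = mean_trace$protocol),
            class = "dff_trace")
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf("dF/F trace: %d frames at %g Hz, range [%.3g, %.3g]%%\n",
              length(x$values), x$frame_rate_hz,
              min(x$values), max(x$values)))
  invisible(x)
}
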