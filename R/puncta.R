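# Baseline-image construction and the transient-size/anatomy correlation.

#' Average pre-stimulus baseline image
#'
#' Pixelwise mean over the pre-stimulus frames of a movie (those within
#' `window_s` before stimulus onset), the image on which punctate anatomy
#' is quantified.
#'
#' @param movie An `"ffn_movie"`.
#' @param protocol A [make_stimulus_protocol()]; frames before its
#'   `onset_s` are averaged. Defaults to the movie's own protocol.
#' @param window_s Length (s) of the pre-stimulus window; `NULL` uses all
#'   frames before onset.
#' @return Object of class `"baseline_image"`: `pixels` (H x W matrix),
#'   `pixel_size_um`, `n_frames`.
#' @export
baseline_image <- function(movie, protocol = NULL, window_s = NULL) {
  stopifnot(inherits(movie, "ffn_movie"))
  if (is.null(protocol)) protocol <- movie$protocol
  stopifnot(inherits(protocol, "stimulus_protocol"))
  d <- dim(movie$frames)
  times <- (seq_len(d[1]) - 1) / movie$frame_rate_hz
  tol <- 1e-9
  sel <- times < protocol$onset_s - tol
  if (!is.null(window_s)) {
    check_scalar(window_s, "window_s", lower = 0, strict_lower = TRUE)
    sel <- sel & times >= protocol$onset_s - window_s - tol
  }
  if (!any(sel)) stop_invalid("no pre-stimulus frames in the window")
  sub <- movie$frames[sel, , , drop = FALSE]
  px <- apply(sub, c(2, 3), mean)
  structure(list(pixels = px, pixel_size_um = movie$pixel_size_um,
                 n_frames = sum(sel)),
            class = "baseline_image")
}

#' Pearson correlation between two per-field measures
#'
#' Sample Pearson correlation, used to relate transient magnitude (AUC)
#' to the Canny edge sum or to initial fluorescence across fields of
#' view. Errors on degenerate (zero-variance) input rather than
#' returning NA.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    stop_invalid("`x` and `y` must be numeric vectors of equal length")
  }
  if (length(x) < 3L) stop_invalid("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop_invalid("missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_invalid("zero variance in `x` or `y`; correlation undefined")
  }
  stats::cor(x, y, method = "pearson")
}
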