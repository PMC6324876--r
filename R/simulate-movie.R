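# Image-level generative model: static punctate anatomy plus a spatially
# diffuse evoked flash whose frame-mean follows simulate_trace().

# 2-D Gaussian punctum profile on the pixel grid (unnormalized peak 1).
punctum_profile <- function(h, w, x, y, sigma_px) {
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)
  exp(-((xs - x)^2 + (ys - y)^2) / (2 * sigma_px^2))
}

#' Simulate a fluorescence movie with known ground truth
#'
#' Builds a T x H x W intensity stack: a flat background plus static 2-D
#' Gaussian puncta (the punctate anatomy visible in baseline images),
#' multiplied by the photobleaching trend, plus a spatially uniform evoked
#' component whose frame-mean reproduces [simulate_trace()] exactly, plus
#' optional per-pixel noise. At `noise_model = "none"` the frame-mean of
#' the movie equals the noiseless simulated trace to machine precision.
#'
#' @inheritParams simulate_trace
#' @param puncta_count Number of puncta, >= 0.
#' @param puncta_positions Optional `puncta_count` x 2 matrix of (x, y)
#'   pixel coordinates in `[1, W] x [1, H]`; drawn uniformly (away from
#'   the border) when omitted.
#' @param punctum_sigma_px Gaussian radius of a punctum, pixels.
#' @param punctum_amplitude Peak intensity of a punctum above background,
#'   as a multiple of the mean baseline intensity.
#' @param height_px,width_px Frame size (default 64 x 64).
#' @param pixel_size_um Pixel pitch (um); 64 px at ~50 um field -> 0.78.
#' @param region_label `"striatum"` or `"GPe"`, carried as metadata.
#' @param noise_model `"none"`, `"gaussian"` (per-pixel SD `noise_sd`), or
#'   `"poisson"` (shot noise; intensities are treated as photon counts).
#' @param noise_sd Per-pixel Gaussian noise SD (intensity units).
#' @return List with `movie` (class `"ffn_movie"`: `frames`,
#'   `frame_rate_hz`, `pixel_size_um`, `region_label`, `protocol`) and
#'   `truth` (class `"ffn_ground_truth"`, including `puncta_positions`
#'   and `puncta_count`).
#' @export
simulate_movie <- function(kinetics, protocol, puncta_count = 10,
                           puncta_positions = NULL,
                           punctum_sigma_px = 1.5,
                           punctum_amplitude = 2,
                           calcium_mM = 2.4, duration_s = 8,
                           frame_rate_hz = 10,
                           height_px = 64, width_px = 64,
                           pixel_size_um = 50 / 64,
                           region_label = c("GPe", "striatum"),
                           noise_model = c("none", "gaussian", "poisson"),
                           noise_sd = 0, seed = NULL) {
  stopifnot(inherits(kinetics, "region_kinetics"),
            inherits(protocol, "stimulus_protocol"))
  region_label <- match.arg(region_label)
  noise_model <- match.arg(noise_model)
  if (!is_scalar_number(puncta_count) || puncta_count < 0 ||
      puncta_count != round(puncta_count)) {
    stop_invalid("`puncta_count` must be a non-negative integer")
  }
  puncta_count <- as.integer(puncta_count)
  seeds <- spawn_seeds(if (is.null(seed)) 1L else seed, 3L)

  if (is.null(puncta_positions)) {
    if (puncta_count > 0L) {
      margin <- ceiling(2 * punctum_sigma_px)
      puncta_positions <- with_seed(seeds[1], cbind(
        x = stats::runif(puncta_count, 1 + margin, width_px - margin),
        y = stats::runif(puncta_count, 1 + margin, height_px - margin)))
    } else {
      puncta_positions <- matrix(numeric(0), ncol = 2,
                                 dimnames = list(NULL, c("x", "y")))
    }
  } else {
    puncta_positions <- as.matrix(puncta_positions)
    if (nrow(puncta_positions) != puncta_count ||
        ncol(puncta_positions) != 2) {
      stop_invalid("`puncta_positions` must be a puncta_count x 2 matrix")
    }
    if (any(puncta_positions[, 1] < 1 | puncta_positions[, 1] > width_px |
            puncta_positions[, 2] < 1 | puncta_positions[, 2] > height_px)) {
      stop_invalid("punctum placed outside the frame")
    }
  }

  # Static spatial profile S(x, y); mean(S) is the trace's F0.
  f0 <- kinetics$baseline_f0
  profile <- matrix(1, height_px, width_px)
  if (puncta_count > 0L) {
    for (i in seq_len(puncta_count)) {
      profile <- profile + punctum_amplitude * punctum_profile(
        height_px, width_px,
        puncta_positions[i, 1], puncta_positions[i, 2], punctum_sigma_px)
    }
  }
  profile <- profile * (f0 / mean(profile))  # mean(S) == baseline_f0

  sim <- simulate_trace(kinetics, protocol, calcium_mM = calcium_mM,
                        duration_s = duration_s,
                        frame_rate_hz = frame_rate_hz, noise_sd = 0)
  times <- sim$raw$times_s
  n_frames <- length(times)
  bleach <- 1 - kinetics$bleach_slope * times
  evoked <- sim$raw$values - f0 * bleach  # uniform evoked intensity/frame

  frames <- array(0, dim = c(n_frames, height_px, width_px))
  for (k in seq_len(n_frames)) {
    frames[k, , ] <- profile * bleach[k] + evoked[k]
  }
  if (noise_model == "gaussian" && noise_sd > 0) {
    frames <- frames + with_seed(seeds[2],
      array(stats::rnorm(length(frames), 0, noise_sd), dim = dim(frames)))
    frames[frames < 0] <- 0
  } else if (noise_model == "poisson") {
    frames <- with_seed(seeds[3],
      array(stats::rpois(length(frames), pmax(frames, 0)),
            dim = dim(frames)))
  }

  truth <- sim$truth
  truth$puncta_positions <- puncta_positions
  truth$puncta_count <- puncta_count
  truth$noise_sd <- if (noise_model == "gaussian") noise_sd else NA_real_
  truth$seed <- seed

  movie <- structure(
    list(frames = frames, frame_rate_hz = frame_rate_hz,
         pixel_size_um = pixel_size_um, region_label = region_label,
         protocol = protocol),
    class = "ffn_movie")
  list(movie = movie, truth = truth)
}

#' @export
print.ffn_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("FFN movie [%s]: %d frames of %dx%d px at %g Hz (%.2f um/px)\n",
              x$region_label, d[1], d[2], d[3], x$frame_rate_hz,
              x$pixel_size_um))
  invisible(x)
}
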