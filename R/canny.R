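# Canny edge detection on baseline images.
#
# Pipeline: Gaussian smoothing -> Sobel gradient -> gradient magnitude
# normalized to max 1 -> non-maximum suppression along the quantized
# gradient direction -> hysteresis thresholding with (low, high) acting
# on the normalized magnitude. Thresholds on the normalized magnitude
# make the mask invariant to additive offsets and multiplicative scaling
# of the image, and reproduce the threshold semantics under which the
# conventional (0.08, 0.2) pair outlines punctate fluorescence.

# Reflect-padded separable Gaussian smoothing.
gaussian_smooth <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-(-r:r)^2 / (2 * sigma_px^2))
  k <- k / sum(k)
  smooth_1d <- function(m) {
    # filter columns of m with kernel k, reflect padding
    n <- nrow(m)
    idx <- c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
    pad <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * pad[(j - 1L) + seq_len(n), , drop = FALSE]
    }
    out
  }
  t(smooth_1d(t(smooth_1d(img))))
}

# Sobel gradients (gy along rows/y, gx along columns/x).
sobel_gradients <- function(img) {
  h <- nrow(img); w <- ncol(img)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- img
  # replicate borders
  pad[1, ] <- pad[2, ]; pad[h + 2, ] <- pad[h + 1, ]
  pad[, 1] <- pad[, 2]; pad[, w + 2] <- pad[, w + 1]
  sh <- function(dy, dx) pad[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1) -
         sh(-1, -1) - 2 * sh(0, -1) - sh(1, -1)) / 8
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1) -
         sh(-1, -1) - 2 * sh(-1, 0) - sh(-1, 1)) / 8
  list(gx = gx, gy = gy)
}

# Non-maximum suppression with gradient direction quantized to 4 sectors.
non_max_suppression <- function(mag, gx, gy) {
  h <- nrow(mag); w <- ncol(mag)
  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- integer(length(ang))
  a <- as.vector(ang)
  sector[a < pi / 8 | a >= 7 * pi / 8] <- 0L        # E-W
  sector[a >= pi / 8 & a < 3 * pi / 8] <- 1L        # NE-SW
  sector[a >= 3 * pi / 8 & a < 5 * pi / 8] <- 2L    # N-S
  sector[a >= 5 * pi / 8 & a < 7 * pi / 8] <- 3L    # NW-SE
  sector <- matrix(sector, h, w)

  padm <- matrix(0, h + 2, w + 2)
  padm[2:(h + 1), 2:(w + 1)] <- mag
  sh <- function(dy, dx) padm[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
  n1 <- matrix(0, h, w); n2 <- matrix(0, h, w)
  for (s in 0:3) {
    off <- switch(s + 1L,
                  list(c(0, 1), c(0, -1)),     # E-W
                  list(c(1, 1), c(-1, -1)),    # NE-SW (row+, col+)
                  list(c(1, 0), c(-1, 0)),     # N-S
                  list(c(1, -1), c(-1, 1)))    # NW-SE
    m <- sector == s
    n1[m] <- sh(off[[1]][1], off[[1]][2])[m]
    n2[m] <- sh(off[[2]][1], off[[2]][2])[m]
  }
  keep <- mag >= n1 & mag >= n2
  out <- mag
  out[!keep] <- 0
  out
}

# Hysteresis: keep weak pixels 8-connected to a strong pixel.
hysteresis <- function(mag_nms, low, high) {
  strong <- mag_nms >= high
  weak <- mag_nms >= low
  if (!any(strong)) return(matrix(0L, nrow(mag_nms), ncol(mag_nms)))
  h <- nrow(mag_nms); w <- ncol(mag_nms)
  mask <- strong
  repeat {
    pad <- matrix(FALSE, h + 2, w + 2)
    pad[2:(h + 1), 2:(w + 1)] <- mask
    grown <- mask
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      grown <- grown | pad[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
    }
    grown <- grown & weak
    if (identical(grown, mask)) break
    mask <- grown
  }
  matrix(as.integer(mask), h, w)
}

#' Canny edge mask of a baseline image
#'
#' Detects high-contrast edges — the outlines of fluorescent puncta and
#' neuropil — in a pre-stimulus baseline image. Thresholds apply to the
#' gradient magnitude normalized to a maximum of 1, so the mask is
#' invariant to additive offsets and to rescaling of the image intensity.
#' A constant image yields an empty mask.
#'
#' @param image A [baseline_image()] or a numeric matrix.
#' @param low,high Hysteresis thresholds in `[0, 1]`, `low < high`.
#'   Defaults (0.08, 0.2) are the conventional values for outlining
#'   punctate fluorescence.
#' @param sigma_px Gaussian pre-smoothing width (px), default 1.4.
#' @return Object of class `"edge_mask"`: `pixels` (0/1 integer matrix),
#'   `low_threshold`, `high_threshold`, `smoothing_sigma_px`.
#' @export
canny_mask <- function(image, low = 0.08, high = 0.2, sigma_px = 1.4) {
  px <- if (inherits(image, "baseline_image")) image$pixels else image
  if (!is.matrix(px) || !is.numeric(px) || any(dim(px) < 3)) {
    stop_invalid("`image` must be a numeric matrix of at least 3 x 3")
  }
  check_scalar(low, "low", lower = 0, upper = 1)
  check_scalar(high, "high", lower = 0, upper = 1)
  if (low >= high) stop_invalid("`low` must be smaller than `high`")
  check_scalar(sigma_px, "sigma_px", lower = 0)

  sm <- gaussian_smooth(px, sigma_px)
  g <- sobel_gradients(sm)
  mag <- sqrt(g$gx^2 + g$gy^2)
  mmax <- max(mag)
  mask <- if (mmax <= .Machine$double.eps * max(abs(px), 1)) {
    matrix(0L, nrow(px), ncol(px))  # constant image: no edges
  } else {
    hysteresis(non_max_suppression(mag / mmax, g$gx, g$gy), low, high)
  }
  structure(list(pixels = mask, low_threshold = low, high_threshold = high,
                 smoothing_sigma_px = sigma_px),
            class = "edge_mask")
}

#' Canny edge sum
#'
#' Number of edge pixels in a mask — the per-field proxy for the amount
#' of punctate structure.
#'
#' @param mask An [canny_mask()] `"edge_mask"` or a 0/1 matrix.
#' @return Integer count of 1-pixels.
#' @export
canny_edge_sum <- function(mask) {
  px <- if (inherits(mask, "edge_mask")) mask$pixels else mask
  if (!all(px %in% c(0L, 1L))) stop_invalid("mask must be binary 0/1")
  sum(px == 1L)
}
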