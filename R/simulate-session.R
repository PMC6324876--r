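# Slice-session generator: fields of view with positions, AUCs and
# hotspot labels, for the spatial hotspot analysis.

#' Simulate a slice imaging session
#'
#' Generates `n_fovs` fields of view within a 2-D slice region of extent
#' `extent_um` (along the long and short axes of the imaged plane). A
#' fraction `hotspot_fraction` of fields are hotspots and draw their
#' transient AUC from the high distribution; the rest draw from the low
#' distribution. Placement is either `"uniform"` (all fields uniform over
#' the extent — hotspots spatially dispersed, the null of the dispersion
#' test) or `"clustered"` (hotspot fields co-located within a disc of
#' radius `cluster_radius_frac` of the extent around a random centre).
#'
#' Canny edge sums and initial fluorescence are drawn independently of the
#' AUC, mirroring the empirical decoupling between transient size and
#' punctate anatomy.
#'
#' @param n_fovs Number of fields of view, >= 1.
#' @param hotspot_fraction Fraction of hotspot fields in `[0, 1]`.
#' @param placement `"uniform"` or `"clustered"`.
#' @param extent_um Length-2 extent (um) of the sampled region; a scalar
#'   is recycled to a square. Must be positive.
#' @param auc_low,auc_high Length-2 `c(meanlog, sdlog)` parameters of the
#'   log-normal AUC distributions for ordinary and hotspot fields
#'   (percent dF/F * s). Defaults put ordinary GPe fields near 2 and
#'   hotspots near striatum-like values around 8.5.
#' @param cluster_radius_frac Radius of the hotspot cluster as a fraction
#'   of the larger extent (clustered placement only).
#' @param canny_lambda Mean of the Poisson edge-sum distribution.
#' @param initial_f_mean,initial_f_sd Normal parameters of the initial
#'   mean fluorescence.
#' @param slice_id Identifier carried on the session.
#' @param region Region label.
#' @param seed Optional integer seed (deterministic session).
#' @return Object of class `"slice_session"`: `slice_id`, `region`,
#'   `extent_um`, and `fovs`, a data.frame with columns `fov_id`, `x_um`,
#'   `y_um`, `auc`, `canny_sum`, `initial_f`, `is_hotspot`.
#' @export
simulate_slice_session <- function(n_fovs, hotspot_fraction = 0.1,
                                   placement = c("uniform", "clustered"),
                                   extent_um = c(1000, 600),
                                   auc_low = c(log(2), 0.5),
                                   auc_high = c(log(8.5), 0.3),
                                   cluster_radius_frac = 0.05,
                                   canny_lambda = 60,
                                   initial_f_mean = 100, initial_f_sd = 10,
                                   slice_id = "slice1",
                                   region = "GPe",
                                   seed = NULL) {
  placement <- match.arg(placement)
  if (!is_scalar_number(n_fovs) || n_fovs < 1 || n_fovs != round(n_fovs)) {
    stop_invalid("`n_fovs` must be a positive integer")
  }
  check_scalar(hotspot_fraction, "hotspot_fraction", lower = 0, upper = 1)
  if (length(extent_um) == 1L) extent_um <- rep(extent_um, 2L)
  if (length(extent_um) != 2L || any(!is.finite(extent_um)) ||
      any(extent_um <= 0)) {
    stop_invalid("`extent_um` must be one or two positive lengths")
  }
  n_fovs <- as.integer(n_fovs)
  n_hot <- round(n_fovs * hotspot_fraction)

  fovs <- with_seed(seed, {
    is_hot <- rep(FALSE, n_fovs)
    if (n_hot > 0) is_hot[sample.int(n_fovs, n_hot)] <- TRUE
    x <- stats::runif(n_fovs, 0, extent_um[1])
    y <- stats::runif(n_fovs, 0, extent_um[2])
    if (placement == "clustered" && n_hot > 0) {
      r <- cluster_radius_frac * max(extent_um)
      cx <- stats::runif(1, r, extent_um[1] - r)
      cy <- stats::runif(1, r, extent_um[2] - r)
      ang <- stats::runif(n_hot, 0, 2 * pi)
      rad <- r * sqrt(stats::runif(n_hot))
      x[is_hot] <- cx + rad * cos(ang)
      y[is_hot] <- cy + rad * sin(ang)
    }
    auc <- numeric(n_fovs)
    auc[!is_hot] <- stats::rlnorm(sum(!is_hot), auc_low[1], auc_low[2])
    auc[is_hot] <- stats::rlnorm(n_hot, auc_high[1], auc_high[2])
    data.frame(
      fov_id = sprintf("fov%03d", seq_len(n_fovs)),
      x_um = x, y_um = y, auc = auc,
      canny_sum = stats::rpois(n_fovs, canny_lambda),
      initial_f = stats::rnorm(n_fovs, initial_f_mean, initial_f_sd),
      is_hotspot = is_hot,
      stringsAsFactors = FALSE)
  })

  structure(list(slice_id = slice_id, region = region,
                 extent_um = extent_um, fovs = fovs),
            class = "slice_session")
}

#' @export
print.slice_session <- function(x, ...) {
  cat(sprintf(
    "Slice session %s [%s]: %d fields of view, %d hotspot(s), %g x %g um\n",
    x$slice_id, x$region, nrow(x$fovs), sum(x$fovs$is_hotspot),
    x$extent_um[1], x$extent_um[2]))
  invisible(x)
}
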