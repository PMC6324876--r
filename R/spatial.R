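# Spatial hotspot analysis: pair distances, quartile classification and
# a permutation test of hotspot clustering.

#' Pairwise distances between fields of view
#'
#' Euclidean distance (um) in the slice plane for every unordered pair of
#' fields of view in a session: `n (n - 1) / 2` entries.
#'
#' @param session A [simulate_slice_session()] `"slice_session"` (or any
#'   list with a `fovs` data.frame carrying `fov_id`, `x_um`, `y_um`).
#' @return data.frame with columns `fov_i`, `fov_j`, `distance_um`; empty
#'   (with a warning) when the session has fewer than 2 fields.
#' @export
pairwise_distances <- function(session) {
  fovs <- session$fovs
  n <- nrow(fovs)
  if (n < 2L) {
    warning("fewer than 2 fields of view; no pairs", call. = FALSE)
    return(data.frame(fov_i = character(0), fov_j = character(0),
                      distance_um = numeric(0)))
  }
  dmat <- as.matrix(stats::dist(fovs[, c("x_um", "y_um")]))
  pr <- which(upper.tri(dmat), arr.ind = TRUE)
  pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
  data.frame(fov_i = fovs$fov_id[pr[, 1]],
             fov_j = fovs$fov_id[pr[, 2]],
             distance_um = dmat[pr],
             stringsAsFactors = FALSE)
}

# Quartile labels (1 = top AUC ... 4 = bottom), stable in input order.
# When n is not divisible by 4, the extra members go to the lower
# (smaller-AUC) quartiles.
assign_auc_quartiles <- function(auc) {
  n <- length(auc)
  base <- n %/% 4L
  sizes <- rep(base, 4L)
  r <- n %% 4L
  if (r > 0L) sizes[seq(4L, by = -1L, length.out = r)] <- base + 1L
  ord <- order(auc, decreasing = TRUE)  # stable: ties keep input order
  q <- integer(n)
  q[ord] <- rep(1:4, times = sizes)
  q
}

#' Quartile pair-distance analysis
#'
#' Ranks the fields of view of a slice by transient AUC, partitions them
#' into four near-equal quartiles (ties broken by stable input order;
#' remainders go to the lower quartiles), and classifies every pair of
#' fields by whether both members fall in the top quartile (both large
#' transients) or both in the bottom quartile. Comparing the top-pair
#' distance distribution with all pairs asks whether high-releasing
#' areas are spatially clustered.
#'
#' @param session A `"slice_session"` with at least 4 fields of view.
#' @return Object of class `"quartile_pair_result"`: `assignment` (FOV id,
#'   AUC, quartile), `all_pairs`, `top_pairs`, `bottom_pairs` (each a
#'   [pairwise_distances()]-style data.frame), and the `session`.
#' @export
quartile_pair_analysis <- function(session) {
  fovs <- session$fovs
  if (nrow(fovs) < 4L) {
    stop_invalid("quartile analysis needs at least 4 fields of view")
  }
  q <- assign_auc_quartiles(fovs$auc)
  pairs <- pairwise_distances(session)
  qi <- q[match(pairs$fov_i, fovs$fov_id)]
  qj <- q[match(pairs$fov_j, fovs$fov_id)]
  structure(list(
    assignment = data.frame(fov_id = fovs$fov_id, auc = fovs$auc,
                            quartile = q, stringsAsFactors = FALSE),
    all_pairs = pairs,
    top_pairs = pairs[qi == 1L & qj == 1L, , drop = FALSE],
    bottom_pairs = pairs[qi == 4L & qj == 4L, , drop = FALSE],
    session = session),
    class = "quartile_pair_result")
}

#' Permutation test of hotspot spatial clustering
#'
#' Tests whether the fields of view with the largest transients sit
#' closer together than expected if transient size were unrelated to
#' position. The statistic is the median distance between top-quartile
#' pairs; the null distribution is obtained by permuting the AUC values
#' across the (fixed) field positions. Small statistics indicate
#' clustering, so the p-value is the fraction of permutations with a
#' median top-pair distance at least as small as observed (with the
#' add-one correction).
#'
#' @param result A [quartile_pair_analysis()] result.
#' @param n_permutations Number of label permutations, >= 1.
#' @param seed Optional integer seed (identical seed, identical p).
#' @return List with `statistic` (median top-pair distance, um),
#'   `p_value`, `n_permutations`, `n_top_pairs`.
#' @export
hotspot_dispersion_test <- function(result, n_permutations = 999,
                                    seed = NULL) {
  stopifnot(inherits(result, "quartile_pair_result"))
  if (!is_scalar_number(n_permutations) || n_permutations < 1) {
    stop_invalid("`n_permutations` must be >= 1")
  }
  n_permutations <- as.integer(n_permutations)
  if (nrow(result$top_pairs) < 1L) {
    stop_invalid("no top-quartile pairs to test")
  }
  fovs <- result$session$fovs
  n <- nrow(fovs)
  dmat <- as.matrix(stats::dist(fovs[, c("x_um", "y_um")]))
  obs <- stats::median(result$top_pairs$distance_um)

  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      perm_auc <- sample(fovs$auc)
      top <- which(assign_auc_quartiles(perm_auc) == 1L)
      sub <- dmat[top, top]
      stats::median(sub[upper.tri(sub)])
    }, numeric(1))
  })
  p <- (1 + sum(perm_stats <= obs + 1e-12)) / (n_permutations + 1)
  list(statistic = obs, p_value = p,
       n_permutations = n_permutations,
       n_top_pairs = nrow(result$top_pairs))
}
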