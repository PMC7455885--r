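# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw from a normal distribution truncated at zero
#'
#' Exact inverse-CDF sampling from N(mean, sd) conditioned on being
#' non-negative. Used for scaled-intensity draws, which are magnitudes.
#'
#' @param n number of draws
#' @param mean,sd parameters of the untruncated normal (sd > 0)
#' @return numeric vector of n non-negative draws
#' @keywords internal
rtnorm0 <- function(n, mean, sd) {
  p0 <- stats::pnorm(0, mean, sd)
  u <- stats::runif(n, p0, 1)
  stats::qnorm(u, mean, sd)
}

#' CDF of the zero-truncated normal
#' @keywords internal
ptnorm0 <- function(q, mean, sd) {
  p0 <- stats::pnorm(0, mean, sd)
  pmax(0, (stats::pnorm(q, mean, sd) - p0) / (1 - p0))
}

# Voxel/world convention: voxel centres sit at world = (index - 1) * spacing
# (0-based logical index times spacing); each voxel owns the half-open box
# [(i - 1.5) s, (i - 0.5) s). world -> index is nearest-centre rounding.
world_to_index <- function(points, spacing) {
  # points: n x 3 matrix of world mm; returns n x 3 integer matrix (1-based)
  idx <- sweep(points, 2, spacing, "/")
  matrix(as.integer(round(idx)), ncol = 3L) + 1L
}

index_in_grid <- function(idx, grid_shape) {
  idx[, 1] >= 1L & idx[, 1] <= grid_shape[1] &
    idx[, 2] >= 1L & idx[, 2] <= grid_shape[2] &
    idx[, 3] >= 1L & idx[, 3] <= grid_shape[3]
}

stop_config <- function(field, msg) {
  stop(sprintf("configuration error in '%s': %s", field, msg), call. = FALSE)
}

stop_geometry <- function(msg) {
  stop(sprintf("geometry error: %s", msg), call. = FALSE)
}

stop_empty_region <- function(what = "mask") {
  stop(sprintf("empty-region error: %s contains no voxels", what), call. = FALSE)
}

assert_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop_config(field, sprintf("must be an integer >= %d", min))
  as.integer(x)
}
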