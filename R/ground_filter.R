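#' Fit a gridded minimum-elevation ground model
#'
#' Divides the x-y plane into square cells of side `cell_size` and records
#' the minimum z of the points in each occupied cell ("the lowest ground
#' points in each small area"). Cells that receive no points are filled
#' with the value of the nearest occupied cell so that any query location
#' has a defined ground elevation.
#'
#' @param cloud a [point_cloud()]; must be nonempty.
#' @param cell_size cell side in m (default 0.25, below the 0.5 m row
#'   spacing so every cell sees real ground).
#' @return An object of class `ground_model`: cell grid origin, size,
#'   dimensions and the per-cell minimum elevation matrix.
#' @export
fit_ground <- function(cloud, cell_size = 0.25) {
  stopifnot(inherits(cloud, "stalk_cloud"), cell_size > 0)
  if (n_points(cloud) == 0L) stop("cannot fit a ground model to an empty cloud")
  x0 <- min(cloud$xyz[, 1]); y0 <- min(cloud$xyz[, 2])
  ix <- floor((cloud$xyz[, 1] - x0) / cell_size) + 1L
  iy <- floor((cloud$xyz[, 2] - y0) / cell_size) + 1L
  nx <- max(ix); ny <- max(iy)
  mz <- matrix(NA_real_, nx, ny)
  ord <- order(cloud$xyz[, 3], decreasing = TRUE)  # later writes win = minima
  mz[cbind(ix[ord], iy[ord])] <- cloud$xyz[ord, 3]
  if (anyNA(mz)) mz <- fill_nearest(mz)
  structure(list(origin = c(x0, y0), cell_size = cell_size,
                 dim = c(nx, ny), min_z = mz),
            class = "ground_model")
}

# Replace NA cells by the value of the nearest (Chebyshev) occupied cell.
fill_nearest <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  na <- which(is.na(m), arr.ind = TRUE)
  occ <- which(!is.na(m), arr.ind = TRUE)
  if (nrow(occ) == 0L) stop("ground model has no occupied cells")
  for (k in seq_len(nrow(na))) {
    d <- pmax(abs(occ[, 1] - na[k, 1]), abs(occ[, 2] - na[k, 2]))
    j <- which.min(d)
    m[na[k, 1], na[k, 2]] <- m[occ[j, 1], occ[j, 2]]
  }
  m
}

# Ground elevation under each point (nearest cell for out-of-extent points).
ground_at <- function(model, xyz) {
  ix <- floor((xyz[, 1] - model$origin[1]) / model$cell_size) + 1L
  iy <- floor((xyz[, 2] - model$origin[2]) / model$cell_size) + 1L
  ix <- pmin(pmax(ix, 1L), model$dim[1])
  iy <- pmin(pmax(iy, 1L), model$dim[2])
  model$min_z[cbind(ix, iy)]
}

#' Remove ground points with a global elevation threshold
#'
#' Keeps exactly the points whose z is at least `threshold` above the
#' minimum elevation of their grid cell; everything within `threshold`
#' (default 0.1 m) of the local minimum is treated as ground and removed.
#'
#' @param cloud a [point_cloud()].
#' @param model a [fit_ground()] model covering the cloud's extent.
#' @param threshold elevation threshold in m (default 0.1).
#' @return A list with `cloud` (the retained points), `removed` (count) and
#'   `kept_idx` (indices of retained points in the input cloud).
#' @export
remove_ground <- function(cloud, model, threshold = 0.1) {
  stopifnot(inherits(model, "ground_model"), threshold >= 0)
  gz <- ground_at(model, cloud$xyz)
  keep <- cloud$xyz[, 3] >= gz + threshold
  list(cloud = cloud_subset(cloud, keep),
       removed = sum(!keep),
       kept_idx = which(keep))
}

#' Normalize point elevations to height above ground
#'
#' Replaces each z by z minus the ground elevation of the point's cell.
#'
#' @inheritParams remove_ground
#' @return A [point_cloud()] with normalized z.
#' @export
normalize_height <- function(cloud, model) {
  stopifnot(inherits(model, "ground_model"))
  out <- cloud
  out$xyz[, 3] <- cloud$xyz[, 3] - ground_at(model, cloud$xyz)
  out
}
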