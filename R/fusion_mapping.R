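#' Filter detections by prediction confidence
#'
#' Keeps only detections whose confidence is strictly greater than
#' `min_conf` ("more than 90%" by default).
#'
#' @param dets list of detections from [detect()].
#' @param min_conf confidence threshold in `[0, 1]` (default 0.9).
#' @return The surviving detections.
#' @export
filter_confidence <- function(dets, min_conf = 0.9) {
  stopifnot(min_conf >= 0, min_conf <= 1)
  Filter(function(d) d$confidence > min_conf, dets)
}

#' Map a 2D stem detection back to 3D seed points
#'
#' The pixel box gives the x and z extent of the stem in the rotated
#' frame, the slice window gives the y slab; the points inside that 3D box
#' are looked up in the rotated frame and reported as indices into the
#' world (unrotated) cloud, whose point order rotation preserves. The seed
#' carries the world-frame centroid and an estimated stem diameter -- the
#' larger of the seed points' x and y spreads, floored at `min_diameter`.
#'
#' @param det a `stem_detection` (its window records the direction).
#' @param window the [slice_window()] the detection's image came from.
#' @param world the unrotated [point_cloud()] the windows were sliced from.
#' @param pixel_size m per pixel of the detection's image (default 0.004).
#' @param min_diameter diameter floor in m (default 0.005).
#' @param rot optional pre-rotated copy of `world` for the window's
#'   direction; supplying it avoids re-rotating the cloud per detection.
#' @return A `stem_seed3d`: fields `idx` (world point indices), `centroid`,
#'   `confidence`, `diameter`, `direction`, `n_points`.
#' @export
map_to_3d <- function(det, window = det$window, world,
                      pixel_size = 0.004, min_diameter = 0.005, rot = NULL) {
  stopifnot(inherits(window, "slice_window"))
  if (is.null(rot)) rot <- rotate_cloud(world, window$direction)
  o <- window$origin
  b <- det$box
  x0 <- o[1] + b$x_min * pixel_size; x1 <- o[1] + b$x_max * pixel_size
  z0 <- o[3] + b$z_min * pixel_size; z1 <- o[3] + b$z_max * pixel_size
  sel <- which(rot$xyz[, 1] >= x0 & rot$xyz[, 1] < x1 &
                 rot$xyz[, 2] >= o[2] & rot$xyz[, 2] < o[2] + window$depth_y &
                 rot$xyz[, 3] >= z0 & rot$xyz[, 3] < z1)
  if (length(sel) == 0L)
    stop("no world point falls inside the mapped detection box; ",
         "detection dropped")
  pts <- world$xyz[sel, , drop = FALSE]
  structure(list(
    idx = sel,
    centroid = colMeans(pts),
    confidence = det$confidence,
    diameter = estimate_stem_diameter(pts, min_diameter),
    direction = window$direction,
    n_points = length(sel)),
    class = "stem_seed3d")
}

#' Estimate a stem diameter from seed points
#'
#' A detection slab thinner than the stem clips the cylinder to a chord, so
#' the raw horizontal spread of the seed points can underestimate a thick
#' stem severely (a rim-grazing slab sees only a narrow band). Following
#' standard TLS stem-diameter practice, a least-squares circle (Kasa fit)
#' is fitted to the horizontal coordinates: it recovers the full diameter
#' from a clipped arc. The raw spread serves as a lower bound and as the
#' fallback when the fit is degenerate (too few points, or nearly straight
#' arcs, as on leaf surfaces); the result is clamped to
#' `[min_diameter, max_diameter]`.
#'
#' @param pts n x 3 matrix of seed points (m).
#' @param min_diameter,max_diameter clamp range in m (defaults 0.005 and
#'   0.04, the plausible stem range for young maize).
#' @return Estimated diameter in m.
#' @export
estimate_stem_diameter <- function(pts, min_diameter = 0.005,
                                   max_diameter = 0.04) {
  spread <- max(diff(range(pts[, 1])), diff(range(pts[, 2])))
  fit <- NA_real_
  if (nrow(pts) >= 8L) {
    x <- pts[, 1] - mean(pts[, 1]); y <- pts[, 2] - mean(pts[, 2])
    sol <- tryCatch(qr.solve(cbind(2 * x, 2 * y, 1), x^2 + y^2),
                    error = function(e) NULL)
    if (!is.null(sol)) {
      r2 <- sol[3] + sol[1]^2 + sol[2]^2
      if (is.finite(r2) && r2 > 0) fit <- 2 * sqrt(r2)
    }
  }
  d <- max(spread, if (is.finite(fit)) min(fit, max_diameter) else 0)
  min(max(d, min_diameter), max_diameter)
}

#' Fuse per-direction seeds, keeping the best detection per stem
#'
#' Seeds whose centroids fall within `merge_radius` of each other in the
#' x-y plane (single linkage, so chains merge) are treated as detections
#' of the same plant; within each group only the seed with the highest
#' confidence survives, ties broken by larger seed-point count and then by
#' lower direction index. The surviving seed's stem diameter is replaced
#' by the median of the diameters estimated by all of the group's member
#' detections: a single slab can graze a thick stem's rim and measure only
#' a sliver, while the multi-view median is robust to such clipped views.
#'
#' @param seeds list of `stem_seed3d`.
#' @param merge_radius grouping radius in m (default 0.1, half the
#'   within-row plant spacing).
#' @return The fused list of seeds (one per group), ordered by x then y of
#'   their centroids for reproducibility.
#' @export
fuse_directions <- function(seeds, merge_radius = 0.1) {
  stopifnot(merge_radius > 0)
  n <- length(seeds)
  if (n <= 1L) return(seeds)
  xy <- t(vapply(seeds, function(s) s$centroid[1:2], numeric(2L)))
  hc <- stats::hclust(stats::dist(xy), method = "single")
  grp <- stats::cutree(hc, h = merge_radius)
  kept <- lapply(split(seq_len(n), grp), function(members) {
    conf <- vapply(seeds[members], `[[`, 1.0, "confidence")
    npts <- vapply(seeds[members], `[[`, 1L, "n_points")
    diridx <- vapply(seeds[members], function(s) s$direction$index, 1L)
    win <- seeds[[members[order(-conf, -npts, diridx)[1L]]]]
    # consensus diameter: single views can graze a thick stem's rim and
    # underestimate badly; the median over all views of this stem is robust
    win$diameter <- stats::median(
      vapply(seeds[members], `[[`, 1.0, "diameter"))
    win
  })
  kept <- unname(kept)
  xy <- t(vapply(kept, function(s) s$centroid[1:2], numeric(2L)))
  kept[order(xy[, 1], xy[, 2])]
}

#' Export seeds as a data frame
#' @param seeds list of `stem_seed3d`.
#' @return data.frame with seed_id, x, y, z, confidence, diameter, n_points.
#' @export
seeds_table <- function(seeds) {
  data.frame(seed_id = seq_along(seeds),
             x = vapply(seeds, function(s) s$centroid[1], 1.0),
             y = vapply(seeds, function(s) s$centroid[2], 1.0),
             z = vapply(seeds, function(s) s$centroid[3], 1.0),
             confidence = vapply(seeds, `[[`, 1.0, "confidence"),
             diameter = vapply(seeds, `[[`, 1.0, "diameter"),
             n_points = vapply(seeds, `[[`, 1L, "n_points"))
}
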