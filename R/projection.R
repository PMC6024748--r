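#' Azimuthal viewing direction
#'
#' One of `n_views` equally spaced viewing directions around the vertical
#' axis; direction `index` corresponds to a rotation by
#' `index * 2 * pi / n_views`.
#'
#' @param index 0-based direction index in `[0, n_views)`.
#' @param n_views number of directions (default 32, i.e. steps of 360/32
#'   degrees).
#' @return An object of class `view_direction` with fields `index`,
#'   `n_views` and `angle` (radians).
#' @export
view_direction <- function(index, n_views = 32L) {
  index <- as.integer(index); n_views <- as.integer(n_views)
  stopifnot(n_views >= 1L, index >= 0L, index < n_views)
  structure(list(index = index, n_views = n_views,
                 angle = index * 2 * pi / n_views),
            class = "view_direction")
}

#' Rotate a cloud into a viewing direction
#'
#' Rotates the cloud about the vertical (z) axis through its x-y centroid
#' by the direction's angle; z values are untouched and the point order is
#' preserved, so indices into the rotated cloud are indices into the
#' original. `source_frame` records the direction.
#'
#' @param cloud a [point_cloud()].
#' @param direction a [view_direction()].
#' @return The rotated [point_cloud()].
#' @export
rotate_cloud <- function(cloud, direction) {
  stopifnot(inherits(direction, "view_direction"))
  if (n_points(cloud) == 0L) return(cloud)
  ctr <- colMeans(cloud$xyz[, 1:2, drop = FALSE])
  out <- cloud
  a <- direction$angle
  dx <- cloud$xyz[, 1] - ctr[1]; dy <- cloud$xyz[, 2] - ctr[2]
  out$xyz[, 1] <- ctr[1] + cos(a) * dx - sin(a) * dy
  out$xyz[, 2] <- ctr[2] + sin(a) * dx + cos(a) * dy
  out$frame <- sprintf("view_%d_of_%d", direction$index, direction$n_views)
  out
}

#' Axis-aligned slice window in a rotated frame
#'
#' A 3D box selecting the points of one depth image: `field_x` x `field_z`
#' in the image plane (default 1.024 m x 1.024 m) and `depth_y` along the
#' viewing axis (0.016 m when slicing a site for testing, 0.256 m for
#' training regions of interest).
#'
#' @param origin numeric `(x0, y0, z0)` of the window's lower corner (m).
#' @param depth_y slab depth along y (m).
#' @param field_x,field_z image-plane extents (m).
#' @param direction the [view_direction()] the window lives in.
#' @return An object of class `slice_window`.
#' @export
slice_window <- function(origin, depth_y, field_x = 1.024, field_z = 1.024,
                         direction = view_direction(0L)) {
  stopifnot(length(origin) == 3L, field_x > 0, field_z > 0, depth_y > 0)
  structure(list(origin = as.numeric(origin), field_x = field_x,
                 field_z = field_z, depth_y = depth_y, direction = direction),
            class = "slice_window")
}

#' Tile a cloud into slice windows
#'
#' Lays a grid of windows over the cloud in its current frame: x strided by
#' `field`, y strided by `depth`, z strided by `field` and anchored at the
#' cloud's minimum z. Every point falls in exactly one window; windows that
#' receive no points are omitted.
#'
#' @param cloud a [point_cloud()] (already rotated if desired).
#' @param field image-plane window size in m (default 1.024).
#' @param depth slab depth in m (default 0.016).
#' @param direction the [view_direction()] recorded on the windows.
#' @return A list of `list(window = slice_window, idx = point indices)`.
#' @export
slice_windows <- function(cloud, field = 1.024, depth = 0.016,
                          direction = view_direction(0L)) {
  stopifnot(field > 0, depth > 0)
  n <- n_points(cloud)
  if (n == 0L) return(list())
  x0 <- min(cloud$xyz[, 1]); y0 <- min(cloud$xyz[, 2]); z0 <- min(cloud$xyz[, 3])
  ix <- floor((cloud$xyz[, 1] - x0) / field)
  iy <- floor((cloud$xyz[, 2] - y0) / depth)
  iz <- floor((cloud$xyz[, 3] - z0) / field)
  key <- paste(ix, iy, iz)
  groups <- split(seq_len(n), key)
  out <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    idx <- groups[[k]]
    i <- c(ix[idx[1L]], iy[idx[1L]], iz[idx[1L]])
    out[[k]] <- list(
      window = slice_window(c(x0 + i[1] * field, y0 + i[2] * depth,
                              z0 + i[3] * field),
                            depth_y = depth, field_x = field, field_z = field,
                            direction = direction),
      idx = idx)
  }
  out
}

#' Compress the points of one window into a depth image
#'
#' Each point maps to the pixel `(floor((x - x0)/pixel_size),
#' floor((z - z0)/pixel_size))`; the pixel's intensity is
#' `1 - (y_nearest - y0)/depth_y`, where `y_nearest` is the smallest y
#' among the pixel's points, so the nearest surface is brightest and empty
#' pixels are exactly 0.
#'
#' @param cloud a [point_cloud()] whose points all lie inside `window`.
#' @param window a [slice_window()].
#' @param pixel_size pixel side in m (default 0.004, giving 256 x 256
#'   images for the 1.024 m field).
#' @return An object of class `depth_image`: `pixels` is an `nz x nx`
#'   matrix (rows = z from the window bottom, cols = x), plus the geometry
#'   needed to invert pixel/meter coordinates.
#' @export
rasterize <- function(cloud, window, pixel_size = 0.004) {
  stopifnot(inherits(window, "slice_window"), pixel_size > 0)
  nx <- as.integer(round(window$field_x / pixel_size))
  nz <- as.integer(round(window$field_z / pixel_size))
  o <- window$origin
  img <- matrix(0, nz, nx)
  n <- n_points(cloud)
  if (n > 0L) {
    px <- floor((cloud$xyz[, 1] - o[1]) / pixel_size)
    pz <- floor((cloud$xyz[, 3] - o[3]) / pixel_size)
    dy <- cloud$xyz[, 2] - o[2]
    if (any(px < 0L | px >= nx | pz < 0L | pz >= nz | dy < 0 |
            dy >= window$depth_y))
      stop("rasterize: point outside window; pre-filter with slice_windows()")
    inten <- 1 - dy / window$depth_y
    ord <- order(inten)                  # brightest written last
    img[cbind(pz[ord] + 1L, px[ord] + 1L)] <- inten[ord]
  }
  structure(list(pixels = img, pixel_size = pixel_size, window = window),
            class = "depth_image")
}

#' @export
print.depth_image <- function(x, ...) {
  cat(sprintf("<depth_image> %d x %d px (%.3f m/px), %d occupied\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              sum(x$pixels > 0)))
  invisible(x)
}

#' Write a depth image as 8-bit grayscale PNG
#' @param image a [rasterize()] depth image.
#' @param path output file.
#' @return `path`, invisibly. Image rows are flipped so that z increases
#'   upward in the viewed file.
#' @export
write_depth_png <- function(image, path) {
  stopifnot(inherits(image, "depth_image"))
  png::writePNG(image$pixels[rev(seq_len(nrow(image$pixels))), , drop = FALSE],
                path)
  invisible(path)
}

# Pixel bounding box (half-open, 0-based) of points in window coordinates.
pixel_bbox <- function(xyz, window, pixel_size) {
  px <- floor((xyz[, 1] - window$origin[1]) / pixel_size)
  pz <- floor((xyz[, 3] - window$origin[3]) / pixel_size)
  box2d(min(px), min(pz), max(px) + 1L, max(pz) + 1L)
}

#' Build labelled stem/plant training samples
#'
#' For every labelled plant and every one of `n_views` viewing directions,
#' crops a region of interest (1.024 m field, `train_depth` deep, centred
#' on the plant in the rotated frame), rasterizes it, and annotates the
#' pixel bounding box of the whole plant and of its stem, the latter being
#' the plant's points whose height above the plant base is below
#' `stem_fraction` (default 1/3) of the plant height.
#'
#' @param cloud a labelled [point_cloud()] (ground = 0 allowed).
#' @param truths list of [plant_truth()] (defines the plant ids used).
#' @param n_views number of viewing directions (default 32).
#' @param field,train_depth ROI extents in m (defaults 1.024 and 0.256).
#' @param pixel_size m per pixel (default 0.004).
#' @param stem_fraction stem labelling height fraction (default 1/3).
#' @param keep_images if `FALSE`, samples carry `image = NULL` (boxes and
#'   window geometry only), which keeps full-site sample generation light.
#' @return A list of `training_sample` objects with fields `image`,
#'   `plant_box`, `stem_box`, `plant_id`, `direction`, `window`. Plants
#'   with no stem points in a view are skipped with a warning.
#' @export
make_training_samples <- function(cloud, truths, n_views = 32L,
                                  field = 1.024, train_depth = 0.256,
                                  pixel_size = 0.004, stem_fraction = 1 / 3,
                                  keep_images = TRUE) {
  stopifnot(!is.null(cloud$label), stem_fraction > 0, stem_fraction < 1)
  ids <- vapply(truths, `[[`, 1L, "plant_id")
  groups <- split(seq_len(n_points(cloud)), cloud$label)
  out <- vector("list", length(ids) * n_views)
  n_out <- 0L
  for (v in seq_len(n_views) - 1L) {
    dir <- view_direction(v, n_views)
    rot <- rotate_cloud(cloud, dir)
    for (i in seq_along(ids)) {
      sel <- groups[[as.character(ids[i])]]
      if (length(sel) == 0L) {
        warning("plant ", ids[i], " has no points; skipped")
        next
      }
      pxyz <- rot$xyz[sel, , drop = FALSE]
      zb <- min(pxyz[, 3])
      h <- max(pxyz[, 3]) - zb
      stem_sel <- pxyz[, 3] - zb < stem_fraction * h
      if (!any(stem_sel)) {
        warning("plant ", ids[i], " has no stem points below ",
                signif(stem_fraction, 3), " of its height; sample skipped")
        next
      }
      ctr <- colMeans(pxyz)
      win <- slice_window(c(ctr[1] - field / 2, ctr[2] - train_depth / 2,
                            zb - 2 * pixel_size),
                          depth_y = train_depth, field_x = field,
                          field_z = field, direction = dir)
      img <- NULL
      if (keep_images) {
        o <- win$origin
        inside <- rot$xyz[, 1] >= o[1] & rot$xyz[, 1] < o[1] + field &
          rot$xyz[, 2] >= o[2] & rot$xyz[, 2] < o[2] + train_depth &
          rot$xyz[, 3] >= o[3] & rot$xyz[, 3] < o[3] + field
        img <- rasterize(cloud_subset(rot, inside), win, pixel_size)
      }
      n_out <- n_out + 1L
      out[[n_out]] <- structure(list(
        image = img,
        plant_box = pixel_bbox(pxyz, win, pixel_size),
        stem_box = pixel_bbox(pxyz[stem_sel, , drop = FALSE], win, pixel_size),
        plant_id = ids[i], direction = dir, window = win),
        class = "training_sample")
    }
  }
  out[seq_len(n_out)]
}
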