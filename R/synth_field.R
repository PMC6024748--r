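#' Synthetic maize-field specification
#'
#' Describes a simulated young-maize field scanned by terrestrial LiDAR:
#' plants on a row/plant grid (0.5 m between rows, 0.2 m within rows) at a
#' preset planting density, each plant a near-vertical stem cylinder plus
#' arcing distichous leaves, standing on a ridge-and-furrow ground surface
#' with micro-topography. The density presets reproduce the magnitudes of
#' the training and test sites the method was developed on:
#'
#' | preset   | density (plants/m2) | nominal area (m2) | plants | height range (m) |
#' |----------|--------------------:|------------------:|-------:|------------------|
#' | sparse   | 2.69                | 23.05             | 62     | 0.13--0.49       |
#' | moderate | 6.19                | 11.48             | 71     | 0.13--0.69       |
#' | dense    | 8.96                | 9.81              | 88     | 0.14--0.73       |
#' | training | 3.35                | 100.48            | 337    | 0.09--0.68       |
#'
#' The plant count is `round(density * area)`; the realized grid area (a
#' multiple of the 0.5 x 0.2 m cell) keeps the realized density within 10%
#' of the preset.
#'
#' @param preset one of `"sparse"`, `"moderate"`, `"dense"`, `"training"`.
#' @param area field area in m2 (defaults to the preset's nominal area).
#' @param row_spacing,plant_spacing grid spacings in m.
#' @param height_range min/max plant height in m (preset default).
#' @param leaf_count_range integer range of leaves per plant.
#' @param point_spacing target inter-point distance on plant surfaces (m).
#' @param ground_spacing target inter-point distance on the ground (m).
#' @param noise_sd per-coordinate Gaussian noise sd (m). The default
#'   0.0005 m reflects the sub-millimeter scanning accuracy of the
#'   phase-shift TLS class this generator emulates (0.3 mm at 10 m), with
#'   margin for close-range beam effects.
#' @param dropout_rate fraction of surface points randomly dropped, an
#'   inexpensive stand-in for occlusion; in `[0, 1)`.
#' @param ground_relief_amp ridge height above the furrows (m). Plants stand
#'   on ridge crests; ridges run along the rows.
#' @param jitter_sd sd of plant-position jitter around grid nodes (m).
#' @param stem_diameter_range optional `(min, max)` in m; when supplied stem
#'   diameters are drawn uniformly from it, otherwise they follow the
#'   allometric default 0.05 x height clamped to `[0.008, 0.03]` m.
#' @param rng_seed integer seed controlling all randomness in
#'   [generate_field()].
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(preset = c("sparse", "moderate", "dense", "training"),
                       area = NULL,
                       row_spacing = 0.5, plant_spacing = 0.2,
                       height_range = NULL,
                       leaf_count_range = c(4L, 8L),
                       point_spacing = 0.003,
                       ground_spacing = 0.01,
                       noise_sd = 0.0005,
                       dropout_rate = 0.10,
                       ground_relief_amp = 0.08,
                       jitter_sd = 0.015,
                       stem_diameter_range = NULL,
                       rng_seed = 1L) {
  preset <- match.arg(preset)
  tab <- list(
    sparse   = list(density = 2.69, area = 23.05, hr = c(0.13, 0.49)),
    moderate = list(density = 6.19, area = 11.48, hr = c(0.13, 0.69)),
    dense    = list(density = 8.96, area = 9.81,  hr = c(0.14, 0.73)),
    training = list(density = 3.35, area = 100.48, hr = c(0.09, 0.68)))[[preset]]
  area <- area %||% tab$area
  height_range <- height_range %||% tab$hr
  stopifnot(row_spacing > 0, plant_spacing > 0, area > 0,
            length(height_range) == 2L, height_range[1] < height_range[2],
            point_spacing > 0, ground_spacing > 0, noise_sd >= 0,
            dropout_rate >= 0, dropout_rate < 1, ground_relief_amp >= 0,
            length(leaf_count_range) == 2L, leaf_count_range[1] >= 0)
  if (!is.null(stem_diameter_range))
    stopifnot(length(stem_diameter_range) == 2L,
              stem_diameter_range[1] > 0,
              stem_diameter_range[1] <= stem_diameter_range[2])
  n_plants <- as.integer(round(tab$density * area))
  side <- sqrt(area)
  n_rows <- max(1L, as.integer(round(side / row_spacing)))
  n_cols <- max(1L, as.integer(round(side / plant_spacing)))
  while (n_rows * n_cols < n_plants) n_cols <- n_cols + 1L
  structure(list(
    preset = preset, density = tab$density, area = area,
    n_plants = n_plants, n_rows = n_rows, n_cols = n_cols,
    row_spacing = row_spacing, plant_spacing = plant_spacing,
    height_range = height_range, leaf_count_range = as.integer(leaf_count_range),
    point_spacing = point_spacing, ground_spacing = ground_spacing,
    noise_sd = noise_sd, dropout_rate = dropout_rate,
    ground_relief_amp = ground_relief_amp, jitter_sd = jitter_sd,
    stem_diameter_range = stem_diameter_range, rng_seed = as.integer(rng_seed)),
    class = "field_spec")
}

#' @export
print.field_spec <- function(x, ...) {
  cat(sprintf(paste0("<field_spec> preset '%s': %d plants, %d x %d grid ",
                     "(%.1f x %.1f m), target density %.2f plants/m2\n"),
              x$preset, x$n_plants, x$n_rows, x$n_cols,
              x$n_rows * x$row_spacing, x$n_cols * x$plant_spacing, x$density))
  invisible(x)
}

#' Ground truth for one synthetic plant
#'
#' @param plant_id positive integer label.
#' @param stem_base numeric `(x, y)` of the stem base in m.
#' @param height plant height in m.
#' @param stem_diameter stem diameter in m.
#' @return An object of class `plant_truth`.
#' @export
plant_truth <- function(plant_id, stem_base, height, stem_diameter) {
  stopifnot(plant_id >= 1L, length(stem_base) == 2L, height > 0,
            stem_diameter > 0)
  structure(list(plant_id = as.integer(plant_id),
                 stem_base = as.numeric(stem_base),
                 height = height, stem_diameter = stem_diameter),
            class = "plant_truth")
}

draw_stem_diameter <- function(height, spec) {
  if (!is.null(spec$stem_diameter_range))
    stats::runif(1L, spec$stem_diameter_range[1], spec$stem_diameter_range[2])
  else
    min(0.03, max(0.008, 0.05 * height * exp(stats::rnorm(1L, 0, 0.08))))
}

# Sample a surface patch: centreline positions `center` (n x 3) with
# horizontal unit lateral direction `lat` (n x 3) and half-widths `hw`,
# at ~`spacing` across the width.
ribbon_points <- function(center, lat, hw, spacing) {
  out <- vector("list", nrow(center))
  for (i in seq_len(nrow(center))) {
    k <- max(2L, ceiling(2 * hw[i] / spacing) + 1L)
    off <- seq(-hw[i], hw[i], length.out = k)
    out[[i]] <- cbind(center[i, 1] + off * lat[i, 1],
                      center[i, 2] + off * lat[i, 2],
                      center[i, 3])
  }
  do.call(rbind, out)
}

#' Generate the point cloud of a single maize plant
#'
#' Builds one plant in the world frame with its stem base at
#' `truth$stem_base` and z = 0 at the base: a near-vertical stem cylinder of
#' the given diameter from the base to ~height/2, and `leaf_count_range`
#' arcing leaves in two opposite ranks (distichous, as in real maize)
#' attached along the upper stem, the topmost reaching the full plant
#' height. Surfaces are sampled at ~`point_spacing`, then Gaussian noise of
#' sd `noise_sd` and random dropout are applied.
#'
#' @param truth a [plant_truth()].
#' @param spec a [field_spec()].
#' @param seed optional integer; when given, the plant is generated under a
#'   private RNG state so the same seed reproduces the same cloud.
#' @param n_leaves optional leaf count override (0 gives a bare stem).
#' @return A [point_cloud()] labelled with `truth$plant_id`.
#' @export
generate_plant <- function(truth, spec, seed = NULL, n_leaves = NULL) {
  stopifnot(inherits(truth, "plant_truth"), inherits(spec, "field_spec"))
  with_seed(seed, {
    h <- truth$height
    hs <- h / 2                       # stem top
    r <- truth$stem_diameter / 2
    sp <- spec$point_spacing
    # stem: near-vertical cylinder (lean kept below 1 degree so every stem
    # point stays within ~stem radius + noise of the vertical axis)
    lean <- stats::runif(1L, 0, 1 * pi / 180)
    lean_az <- stats::runif(1L, 0, 2 * pi)
    zs <- seq(0, hs, by = sp)
    n_ang <- max(6L, ceiling(pi * truth$stem_diameter / sp))
    ang <- seq(0, 2 * pi, length.out = n_ang + 1L)[-1L]
    g <- expand.grid(z = zs, a = ang)
    stem <- cbind(truth$stem_base[1] + g$z * tan(lean) * cos(lean_az) +
                    r * cos(g$a),
                  truth$stem_base[2] + g$z * tan(lean) * sin(lean_az) +
                    r * sin(g$a),
                  g$z)
    pts <- list(stem)
    nl <- n_leaves %||%
      (if (spec$leaf_count_range[1] >= spec$leaf_count_range[2])
         spec$leaf_count_range[1]
       else sample(spec$leaf_count_range[1]:spec$leaf_count_range[2], 1L))
    if (nl > 0L) {
      rank_az <- stats::runif(1L, 0, 2 * pi)   # distichous rank line
      # attachments along the upper stem; the last (topmost) leaf reaches h
      za <- hs * seq(0.45, 0.95, length.out = nl)
      for (i in seq_len(nl)) {
        az <- rank_az + (i %% 2L) * pi + stats::rnorm(1L, 0, 8 * pi / 180)
        dirv <- c(cos(az), sin(az))
        apex_z <- if (i == nl) h else
          za[i] + stats::runif(1L, 0.35, 0.65) * (h - za[i])
        rise <- apex_z - za[i]
        reach <- max(0.06, stats::runif(1L, 0.28, 0.42) * h)
        s_apex <- 0.65 * reach
        s <- sort(c(seq(0, reach, by = sp), s_apex))  # sample the apex exactly
        u <- s / s_apex
        zc <- za[i] + rise * (2 * u - u^2)
        base_xy <- truth$stem_base +
          za[i] * tan(lean) * c(cos(lean_az), sin(lean_az)) + r * dirv
        center <- cbind(base_xy[1] + s * dirv[1], base_xy[2] + s * dirv[2], zc)
        w0 <- stats::runif(1L, 0.018, 0.03)
        hw <- pmax(0.003, w0 * (0.25 + 1.25 * pmin(s / reach, 0.45)) *
                            (1 - 0.7 * pmax(s / reach - 0.55, 0) / 0.45)) / 2
        lat <- cbind(rep(-dirv[2], length(s)), rep(dirv[1], length(s)), 0)
        pts[[length(pts) + 1L]] <- ribbon_points(center, lat, hw, sp)
      }
    }
    xyz <- do.call(rbind, pts)
    if (spec$noise_sd > 0)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, spec$noise_sd),
                          ncol = 3L)
    if (spec$dropout_rate > 0) {
      keep <- stats::runif(nrow(xyz)) >= spec$dropout_rate
      # never drop the whole stem base region
      xyz <- xyz[keep, , drop = FALSE]
    }
    point_cloud(xyz, label = rep(truth$plant_id, nrow(xyz)))
  })
}

# Ridge-and-furrow relief: ridges of height `amp` run along the rows
# (constant y), half-width `hw` < row_spacing/2, plus a gentle large-scale
# undulation. x measured from the first row.
ground_relief <- function(x, y, spec, hw = 0.10) {
  dx <- x - round(x / spec$row_spacing) * spec$row_spacing
  ridge <- ifelse(abs(dx) < hw,
                  spec$ground_relief_amp * cos(pi * dx / (2 * hw))^2, 0)
  und <- if (spec$ground_relief_amp > 0)
    0.01 * sin(x / 1.7) * cos(y / 2.3) else 0
  ridge + und
}

#' Generate a labelled synthetic maize field
#'
#' Places `spec$n_plants` plants on the row/plant grid (random occupied
#' nodes, small positional jitter), each on top of the ridge running along
#' its row, and adds a ground surface (label 0) with ridge-and-furrow
#' relief of amplitude `ground_relief_amp` plus mm-scale roughness. All
#' randomness is governed by `spec$rng_seed`.
#'
#' @param spec a [field_spec()].
#' @return A list with elements `cloud` (labelled [point_cloud()], ground =
#'   label 0) and `truths` (list of [plant_truth()], one per plant).
#' @export
generate_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  if (spec$n_plants < 1L) stop("degenerate field: 0 plants")
  with_seed(spec$rng_seed, {
    nodes <- expand.grid(row = seq_len(spec$n_rows) - 1L,
                         col = seq_len(spec$n_cols) - 1L)
    occ <- nodes[sample.int(nrow(nodes), spec$n_plants), ]
    truths <- vector("list", spec$n_plants)
    plants <- vector("list", spec$n_plants)
    for (i in seq_len(spec$n_plants)) {
      bx <- occ$row[i] * spec$row_spacing +
        stats::rnorm(1L, 0, spec$jitter_sd / 2)   # stay near the ridge crest
      by <- occ$col[i] * spec$plant_spacing +
        stats::rnorm(1L, 0, spec$jitter_sd)
      h <- stats::runif(1L, spec$height_range[1], spec$height_range[2])
      d <- draw_stem_diameter(h, spec)
      truths[[i]] <- plant_truth(i, c(bx, by), h, d)
      p <- generate_plant(truths[[i]], spec)
      p$xyz[, 3] <- p$xyz[, 3] + ground_relief(bx, by, spec)
      plants[[i]] <- p
    }
    ext_x <- c(-spec$row_spacing / 2,
               (spec$n_rows - 0.5) * spec$row_spacing)
    ext_y <- c(-spec$plant_spacing / 2,
               (spec$n_cols - 0.5) * spec$plant_spacing)
    gx <- seq(ext_x[1], ext_x[2], by = spec$ground_spacing)
    gy <- seq(ext_y[1], ext_y[2], by = spec$ground_spacing)
    gg <- expand.grid(x = gx, y = gy)
    gz <- ground_relief(gg$x, gg$y, spec) +
      stats::rnorm(nrow(gg), 0, max(spec$noise_sd, 0.003))
    ground <- cbind(gg$x, gg$y, gz)
    if (spec$dropout_rate > 0)
      ground <- ground[stats::runif(nrow(ground)) >= spec$dropout_rate, ,
                       drop = FALSE]
    xyz <- rbind(do.call(rbind, lapply(plants, `[[`, "xyz")), ground)
    label <- c(unlist(lapply(plants, `[[`, "label")),
               rep(0L, nrow(ground)))
    list(cloud = point_cloud(xyz, label = label), truths = truths)
  })
}

#' Export plant truths as a data frame
#' @param truths list of [plant_truth()] objects.
#' @return data.frame with plant_id, x, y, height, diameter.
#' @export
truths_table <- function(truths) {
  data.frame(plant_id = vapply(truths, `[[`, 1L, "plant_id"),
             x = vapply(truths, function(t) t$stem_base[1], 1.0),
             y = vapply(truths, function(t) t$stem_base[2], 1.0),
             height = vapply(truths, `[[`, 1.0, "height"),
             diameter = vapply(truths, `[[`, 1.0, "stem_diameter"))
}
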