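#' 2D pixel bounding box
#'
#' Half-open, 0-based pixel box: a pixel `(px, pz)` is inside when
#' `x_min <= px < x_max` and `z_min <= pz < z_max`.
#'
#' @param x_min,z_min,x_max,z_max box edges in pixels; `x_max > x_min`,
#'   `z_max > z_min`.
#' @return An object of class `box2d`.
#' @export
box2d <- function(x_min, z_min, x_max, z_max) {
  stopifnot(x_max > x_min, z_max > z_min)
  structure(list(x_min = x_min, z_min = z_min, x_max = x_max, z_max = z_max),
            class = "box2d")
}

box_width <- function(b) b$x_max - b$x_min
box_height <- function(b) b$z_max - b$z_min
box_area <- function(b) box_width(b) * box_height(b)

#' Intersection-over-union of two boxes
#'
#' The degree of overlap used for anchor labelling: intersection area over
#' union area, in `[0, 1]`.
#'
#' @param a,b [box2d()] objects.
#' @return A fraction in `[0, 1]`.
#' @export
iou <- function(a, b) {
  iw <- min(a$x_max, b$x_max) - max(a$x_min, b$x_min)
  ih <- min(a$z_max, b$z_max) - max(a$z_min, b$z_min)
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (box_area(a) + box_area(b) - inter)
}

#' Anchor scheme configuration
#'
#' The anchor set is the Cartesian product of pixel `areas` and aspect
#' `ratios` (height/width); the defaults (4 areas x 5 ratios = 20 anchors
#' per location) follow the detector this package's contract is modelled
#' on. Overlaps above `fg_iou` label an anchor foreground, below `bg_iou`
#' background; the band between is ignored during training.
#'
#' @param areas pixel areas (default `c(1, 7, 14, 59)^2`).
#' @param ratios aspect ratios (default `c(0.13, 0.51, 0.84, 1.3, 8)`).
#' @param fg_iou,bg_iou foreground/background IoU thresholds (0.7 / 0.3).
#' @return An object of class `anchor_config`.
#' @export
anchor_config <- function(areas = c(1, 7, 14, 59)^2,
                          ratios = c(0.13, 0.51, 0.84, 1.3, 8),
                          fg_iou = 0.7, bg_iou = 0.3) {
  stopifnot(length(areas) >= 1L, length(ratios) >= 1L, all(areas > 0),
            all(ratios > 0), bg_iou > 0, bg_iou < fg_iou, fg_iou < 1)
  structure(list(areas = areas, ratios = ratios,
                 fg_iou = fg_iou, bg_iou = bg_iou),
            class = "anchor_config")
}

#' Anchor widths and heights for a configuration
#' @param cfg an [anchor_config()].
#' @return data.frame of `width`, `height`, `area`, `ratio` rows (one per
#'   anchor shape, `|areas| * |ratios|` in total).
#' @export
anchor_shapes <- function(cfg) {
  g <- expand.grid(area = cfg$areas, ratio = cfg$ratios)
  w <- sqrt(g$area / g$ratio)
  data.frame(width = w, height = w * g$ratio, area = g$area, ratio = g$ratio)
}

#' Label anchors against a ground-truth box
#'
#' The anchor with the largest overlap with the target is always
#' foreground; additionally any anchor with IoU above `cfg$fg_iou` is
#' foreground, any below `cfg$bg_iou` background, and the rest are ignored.
#' Foreground anchors receive the standard box-regression offsets: centre
#' shifts normalized by the anchor size and log scale factors.
#'
#' @param anchors list of [box2d()] (at least one).
#' @param gt the ground-truth [box2d()].
#' @param cfg an [anchor_config()].
#' @return data.frame with `label` (factor foreground/background/ignore),
#'   `iou`, and regression targets `dx`, `dz`, `dw`, `dh` (NA for
#'   non-foreground anchors).
#' @export
label_anchors <- function(anchors, gt, cfg = anchor_config()) {
  stopifnot(length(anchors) >= 1L)
  ious <- vapply(anchors, iou, 1.0, b = gt)
  lab <- rep("ignore", length(anchors))
  lab[ious > cfg$fg_iou] <- "foreground"
  lab[ious < cfg$bg_iou] <- "background"
  lab[which.max(ious)] <- "foreground"   # max-overlap anchor is never negative
  res <- data.frame(label = factor(lab, c("foreground", "background", "ignore")),
                    iou = ious, dx = NA_real_, dz = NA_real_,
                    dw = NA_real_, dh = NA_real_)
  fg <- which(lab == "foreground")
  gw <- box_width(gt); gh <- box_height(gt)
  gcx <- (gt$x_min + gt$x_max) / 2; gcz <- (gt$z_min + gt$z_max) / 2
  for (i in fg) {
    a <- anchors[[i]]
    aw <- box_width(a); ah <- box_height(a)
    res$dx[i] <- (gcx - (a$x_min + a$x_max) / 2) / aw
    res$dz[i] <- (gcz - (a$z_min + a$z_max) / 2) / ah
    res$dw[i] <- log(gw / aw)
    res$dh[i] <- log(gh / ah)
  }
  res
}

#' Baseline detector configuration
#'
#' Geometry filters for the deterministic stem detector: candidate
#' connected components must be no wider than `w_max` m, at least `h_min` m
#' tall, at least `r_min` times taller than wide, and must start in the
#' bottom `bottom_frac` of the image's occupied z-range.
#'
#' @param w_max maximum box width in m (default 0.05).
#' @param h_min minimum box height in m (default 0.05).
#' @param r_min minimum height/width ratio (default 2).
#' @param bottom_frac bottom fraction of the occupied z-range in which the
#'   component must begin (default 0.25).
#' @param min_points smallest number of occupied pixels worth examining;
#'   images with fewer are skipped outright (performance knob).
#' @return An object of class `baseline_config`.
#' @export
baseline_config <- function(w_max = 0.05, h_min = 0.05, r_min = 2,
                            bottom_frac = 0.25, min_points = 12L) {
  stopifnot(w_max > 0, h_min > 0, r_min > 0, bottom_frac > 0,
            bottom_frac <= 1)
  structure(list(w_max = w_max, h_min = h_min, r_min = r_min,
                 bottom_frac = bottom_frac, min_points = as.integer(min_points)),
            class = "baseline_config")
}

# 8-connectivity labelling: EBImage::bwlabel is 4-connected, so merge
# labels that touch diagonally.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  nr <- nrow(lab); nc <- ncol(lab)
  if (nr > 1L && nc > 1L) {
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]     # down-right diagonal
    a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]    # down-left diagonal
    sel1 <- a1 > 0 & b1 > 0 & a1 != b1
    sel2 <- a2 > 0 & b2 > 0 & a2 != b2
    pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
    if (nrow(pairs) > 0L) {
      g <- igraph::graph_from_edgelist(matrix(as.character(pairs), ncol = 2L),
                                       directed = FALSE)
      comp <- igraph::components(g)
      remap <- seq_len(max(lab))
      remap[as.integer(igraph::V(g)$name)] <-
        max(lab) + comp$membership   # unique merged ids
      lab[lab > 0] <- remap[lab[lab > 0]]
    }
  }
  lab
}

#' Deterministic geometric stem detector
#'
#' Reference detector backend: binarizes the depth image (intensity > 0),
#' finds 8-connected components, and keeps those shaped like a stem seen
#' from the side -- a narrow, tall, upright bar starting near the bottom of
#' the image content (see [baseline_config()]). Each surviving component
#' becomes a detection whose box is the component's pixel bounding box and
#' whose confidence is
#' `clamp01(0.5 * elongation + 0.5 * fill)`, with
#' `elongation = min(1, (h/w)/4)` and `fill` the fraction of the box
#' covered by component pixels: only dense, strongly elongated bars --
#' stems, not leaf arcs -- approach 1.
#'
#' @param image a [rasterize()] depth image.
#' @param params a [baseline_config()].
#' @return A list of `stem_detection` objects (possibly empty), each with
#'   fields `box` ([box2d()]), `confidence` and `window`.
#' @export
detect_baseline <- function(image, params = baseline_config()) {
  stopifnot(inherits(image, "depth_image"))
  px_m <- image$pixel_size
  occ <- image$pixels > 0
  n_occ <- sum(occ)
  if (n_occ < params$min_points) return(list())
  # crop to the occupied region; component labels are unaffected
  rr <- range(which(rowSums(occ) > 0)); cc <- range(which(colSums(occ) > 0))
  sub <- occ[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  lab <- label_components8(sub)
  z_lo <- rr[1]; z_hi <- rr[2]          # occupied z-range (rows = z)
  z_cut <- z_lo + params$bottom_frac * (z_hi - z_lo)
  w_max <- params$w_max / px_m; h_min <- params$h_min / px_m
  out <- list()
  for (id in setdiff(unique(as.vector(lab)), 0)) {
    cells <- which(lab == id, arr.ind = TRUE)
    zmin <- min(cells[, 1]) + rr[1] - 1L; zmax <- max(cells[, 1]) + rr[1] - 1L
    xmin <- min(cells[, 2]) + cc[1] - 1L; xmax <- max(cells[, 2]) + cc[1] - 1L
    w <- xmax - xmin + 1L; h <- zmax - zmin + 1L
    if (w > w_max || h < h_min || h / w < params$r_min || zmin > z_cut) next
    fill <- nrow(cells) / (w * h)
    conf <- min(1, max(0, 0.5 * min(1, (h / w) / 4) + 0.5 * fill))
    out[[length(out) + 1L]] <- structure(
      list(box = box2d(xmin - 1L, zmin - 1L, xmax, zmax),
           confidence = conf, window = image$window),
      class = "stem_detection")
  }
  out
}

#' Detect stems on a depth image through a backend
#'
#' Dispatches to the baseline geometric detector (a [baseline_config()])
#' or to a trained learned backend honouring the same signature.
#'
#' @param image a [rasterize()] depth image.
#' @param backend a [baseline_config()] or a trained detector handle.
#' @return A list of `stem_detection` objects.
#' @export
detect <- function(image, backend = baseline_config()) {
  if (inherits(backend, "baseline_config")) return(detect_baseline(image, backend))
  if (inherits(backend, "learned_backend")) {
    if (!isTRUE(backend$trained))
      stop("learned detector backend has not been trained")
    return(backend$predict(image))
  }
  stop("unknown detector backend of class ", paste(class(backend), collapse = "/"))
}

#' Training configuration for a learned detector backend
#'
#' @param base_lr base learning rate (default 0.01).
#' @param momentum SGD momentum (default 0.9).
#' @param weight_decay L2 weight decay (default 5e-4).
#' @param stop_loss stop when classification and regression losses both
#'   fall below this (default 0.01).
#' @param max_epochs training-epoch cap.
#' @return An object of class `train_config`.
#' @export
train_config <- function(base_lr = 0.01, momentum = 0.9,
                         weight_decay = 5e-4, stop_loss = 0.01,
                         max_epochs = 1000L) {
  stopifnot(base_lr > 0, momentum > 0, weight_decay > 0, stop_loss > 0,
            max_epochs > 0)
  structure(list(base_lr = base_lr, momentum = momentum,
                 weight_decay = weight_decay, stop_loss = stop_loss,
                 max_epochs = as.integer(max_epochs)),
            class = "train_config")
}

#' Train a learned detector backend
#'
#' Contract for an anchor-based convolutional stem detector trained on
#' [make_training_samples()] output. Training a network requires a
#' deep-learning engine, which this package does not ship; calling this
#' function therefore validates its inputs and then raises a capability
#' error. The deterministic [detect_baseline()] backend is the supported
#' reference implementation of the [detect()] contract.
#'
#' @param samples nonempty list of training samples.
#' @param anchor_cfg an [anchor_config()].
#' @param train_cfg a [train_config()].
#' @param engine name of the deep-learning engine to use.
#' @return (Would return a trained `learned_backend` handle.)
#' @export
train_learned_backend <- function(samples, anchor_cfg = anchor_config(),
                                  train_cfg = train_config(),
                                  engine = "torch") {
  if (length(samples) == 0L) stop("cannot train a detector on 0 samples")
  stopifnot(inherits(anchor_cfg, "anchor_config"),
            inherits(train_cfg, "train_config"))
  if (!requireNamespace(engine, quietly = TRUE))
    stop("training a learned detector backend requires the optional '",
         engine, "' engine, which is not installed; use the baseline ",
         "backend (see detect_baseline)", call. = FALSE)
  stop("no trainer is implemented for engine '", engine, "'", call. = FALSE)
}
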