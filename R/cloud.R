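#' Point cloud container
#'
#' A `stalk_cloud` holds per-point coordinates in meters plus an optional
#' per-point integer plant label (0 = ground/unassigned) and the identifier
#' of the rotation frame the coordinates live in (`"world"` by default).
#' It is the universal currency of the pipeline: every stage consumes and
#' returns one.
#'
#' @param xyz numeric matrix with three columns (x, y, z) in meters, or a
#'   data frame coercible to one. Zero rows are allowed.
#' @param label optional integer vector of per-point plant labels
#'   (non-negative; 0 is reserved for "no plant").
#' @param frame identifier of the coordinate frame, `"world"` by default.
#' @return An object of class `stalk_cloud`: a list with elements `xyz`
#'   (n x 3 matrix), `label` (integer vector or `NULL`) and `frame`.
#' @examples
#' pc <- point_cloud(cbind(runif(5), runif(5), runif(5)))
#' n_points(pc)
#' @export
point_cloud <- function(xyz, label = NULL, frame = "world") {
  if (is.data.frame(xyz)) xyz <- as.matrix(xyz)
  if (length(xyz) == 0L) xyz <- matrix(numeric(0), ncol = 3L)
  if (!is.matrix(xyz) || ncol(xyz) != 3L)
    stop("`xyz` must be an n x 3 matrix of coordinates in meters")
  storage.mode(xyz) <- "double"
  if (nrow(xyz) > 0L && !all(is.finite(xyz)))
    stop("all coordinates must be finite")
  colnames(xyz) <- c("x", "y", "z")
  if (!is.null(label)) {
    if (length(label) != nrow(xyz))
      stop("`label` must have one entry per point (",
           length(label), " != ", nrow(xyz), ")")
    label <- as.integer(label)
    if (anyNA(label) || any(label < 0L))
      stop("plant labels must be non-negative integers (0 = no plant)")
  }
  structure(list(xyz = xyz, label = label, frame = frame),
            class = "stalk_cloud")
}

#' Number of points in a cloud
#' @param cloud a [point_cloud()] object.
#' @return Integer point count.
#' @export
n_points <- function(cloud) nrow(cloud$xyz)

#' Subset a cloud by point index
#' @param cloud a [point_cloud()] object.
#' @param idx integer or logical index into the points.
#' @return A `stalk_cloud` with the selected points (labels carried along).
#' @export
cloud_subset <- function(cloud, idx) {
  point_cloud(cloud$xyz[idx, , drop = FALSE],
              label = if (!is.null(cloud$label)) cloud$label[idx],
              frame = cloud$frame)
}

#' @export
print.stalk_cloud <- function(x, ...) {
  cat("<stalk_cloud> ", n_points(x), " points, frame '", x$frame, "'",
      if (!is.null(x$label))
        paste0(", ", length(setdiff(unique(x$label), 0L)), " labelled plants"),
      "\n", sep = "")
  if (n_points(x) > 0L) {
    rg <- apply(x$xyz, 2L, range)
    cat(sprintf("  extent x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f] m\n",
                rg[1, 1], rg[2, 1], rg[1, 2], rg[2, 2], rg[1, 3], rg[2, 3]))
  }
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards. With seed = NULL the
# global stream is used as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
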