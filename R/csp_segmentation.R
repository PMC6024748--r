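#' Build a k-nearest-neighbour graph over a cloud
#'
#' Connects every point to its `k` nearest neighbours within `radius_cap`
#' (edges longer than the cap are never created, so plants cannot
#' short-circuit through open air), then symmetrizes the edge set. Edge
#' weights are Euclidean distances in meters.
#'
#' @param cloud a [point_cloud()]; must be nonempty.
#' @param k neighbours per point (default 10).
#' @param radius_cap maximum edge length in m (default 0.05, well below
#'   the 0.2 m within-row plant spacing).
#' @return An object of class `neighbor_graph`: `edges` (two-column index
#'   matrix, i < j), `weights`, `n_vertices`, `k`, `radius_cap`.
#' @export
build_graph <- function(cloud, k = 10L, radius_cap = 0.05) {
  stopifnot(inherits(cloud, "stalk_cloud"), k >= 1L, radius_cap > 0)
  n <- n_points(cloud)
  if (n == 0L) stop("cannot build a neighbour graph on an empty cloud")
  e <- knn_edges(cloud$xyz, as.integer(k), radius_cap)
  # symmetrize: undirected unique pairs
  i <- pmin(e$i, e$j); j <- pmax(e$i, e$j)
  dup <- duplicated(cbind(i, j))
  structure(list(edges = cbind(i = i[!dup], j = j[!dup]),
                 weights = e$w[!dup],
                 n_vertices = n, k = as.integer(k), radius_cap = radius_cap),
            class = "neighbor_graph")
}

graph_as_igraph <- function(graph, extra_vertices = 0L) {
  igraph::make_graph(t(graph$edges), directed = FALSE,
                     n = graph$n_vertices + extra_vertices)
}

#' Multi-source transport distances from seeds
#'
#' For every point and every seed, the graph shortest-path distance from
#' the point to the nearest member of the seed's point set (Dijkstra via a
#' zero-weight virtual vertex per seed). Unreachable points get `Inf`.
#'
#' @param graph a [build_graph()] result.
#' @param seeds list of `stem_seed3d` whose `idx` index the graph's cloud.
#' @return Numeric matrix `length(seeds)` x `n_vertices` of distances in m.
#' @export
transport_distances <- function(graph, seeds) {
  stopifnot(inherits(graph, "neighbor_graph"), length(seeds) >= 1L)
  ns <- length(seeds)
  for (s in seeds)
    if (any(s$idx < 1L | s$idx > graph$n_vertices))
      stop("seed point index outside the graph")
  # directed graph with each cloud edge in both directions and one virtual
  # source per seed whose zero-weight arcs point outward only, so a path
  # for one seed can never shortcut through another seed's virtual hub
  virt <- graph$n_vertices + seq_len(ns)
  ve <- do.call(rbind, lapply(seq_len(ns), function(s)
    cbind(virt[s], seeds[[s]]$idx)))
  arcs <- rbind(graph$edges, graph$edges[, 2:1, drop = FALSE], ve)
  g <- igraph::make_graph(t(arcs), directed = TRUE,
                          n = graph$n_vertices + ns)
  w <- c(graph$weights, graph$weights, rep(0, nrow(ve)))
  d <- igraph::distances(g, v = virt, mode = "out", weights = w,
                         algorithm = "dijkstra")
  d[, seq_len(graph$n_vertices), drop = FALSE]
}

#' Assign points to seeds by diameter-scaled distance
#'
#' Implements the comparative shortest-path rule: each point's transport
#' distance to a seed is scaled by that seed's stem diameter to the power
#' 2/3, `DvN = Dv / diameter^(2/3)`, and the point is assigned to the seed
#' minimizing DvN (ties to the lowest seed id; unreachable points stay 0).
#' Scaling by diameter lets thick-stemmed plants claim proportionally more
#' distant points, mirroring metabolic-scaling allometry.
#'
#' @param distances matrix from [transport_distances()] (seeds x points).
#' @param seeds the seed list the distances were computed for.
#' @param exponent the diameter exponent (default 2/3; exposed for
#'   sensitivity analysis).
#' @return An object of class `segmentation_result`: `label` (per-point
#'   seed id, 0 = unassigned), `dvn` (winning scaled distance, Inf where
#'   unassigned), `seeds`.
#' @export
assign_labels <- function(distances, seeds, exponent = 2 / 3) {
  stopifnot(is.matrix(distances), nrow(distances) == length(seeds))
  diam <- vapply(seeds, `[[`, 1.0, "diameter")
  n <- ncol(distances)
  best <- rep(Inf, n); lab <- integer(n)
  for (s in seq_along(seeds)) {
    dvn <- distances[s, ] / diam[s]^exponent
    better <- dvn < best          # strict: ties keep the lower seed id
    best[better] <- dvn[better]
    lab[better] <- s
  }
  structure(list(label = lab, dvn = best, seeds = seeds),
            class = "segmentation_result")
}

#' Segment a cloud by comparative shortest-path region growing
#'
#' Composition of [build_graph()], [transport_distances()] and
#' [assign_labels()]: grows every plant bottom-up from its stem seed
#' points, assigning each non-ground point to the seed that minimizes the
#' diameter-scaled transport distance.
#'
#' @param cloud the ground-removed [point_cloud()] to segment.
#' @param seeds nonempty list of `stem_seed3d` indexing `cloud`.
#' @param k,radius_cap neighbour-graph parameters (see [build_graph()]).
#' @param exponent diameter exponent (default 2/3).
#' @return A `segmentation_result` (see [assign_labels()]).
#' @export
segment <- function(cloud, seeds, k = 10L, radius_cap = 0.05,
                    exponent = 2 / 3) {
  if (length(seeds) == 0L) stop("no seeds to grow from")
  graph <- build_graph(cloud, k = k, radius_cap = radius_cap)
  d <- transport_distances(graph, seeds)
  assign_labels(d, seeds, exponent = exponent)
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d points, %d plants, %d unassigned\n",
              length(x$label), length(x$seeds), sum(x$label == 0L)))
  invisible(x)
}
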