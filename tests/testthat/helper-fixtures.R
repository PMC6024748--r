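# Shared fixtures, built in code at test time.

random_cloud <- function(n, seed = 1, labelled = FALSE, extent = 1) {
  set.seed(seed)
  point_cloud(matrix(runif(3 * n, 0, extent), ncol = 3),
              label = if (labelled) sample(0:5, n, replace = TRUE))
}

# A depth image containing a single solid bar of occupied pixels.
bar_image <- function(x0, z0, w, h, nx = 256, nz = 256, intensity = 0.8) {
  px <- matrix(0, nz, nx)
  px[z0 + seq_len(h), x0 + seq_len(w)] <- intensity
  structure(list(pixels = px, pixel_size = 0.004,
                 window = slice_window(c(0, 0, 0), depth_y = 0.016,
                                       field_x = nx * 0.004,
                                       field_z = nz * 0.004)),
            class = "depth_image")
}

# Two bare noiseless plants on flat ground, labelled, plus their truths.
two_plant_cloud <- function(sep = 0.5, heights = c(0.3, 0.4)) {
  spec <- field_spec("sparse", noise_sd = 0, dropout_rate = 0,
                     ground_relief_amp = 0)
  t1 <- plant_truth(1L, c(0, 0), heights[1], 0.02)
  t2 <- plant_truth(2L, c(sep, 0), heights[2], 0.025)
  p1 <- generate_plant(t1, spec, seed = 11)
  p2 <- generate_plant(t2, spec, seed = 12)
  cloud <- point_cloud(rbind(p1$xyz, p2$xyz), label = c(p1$label, p2$label))
  list(cloud = cloud, truths = list(t1, t2), spec = spec)
}

# Independent Floyd-Warshall all-pairs shortest paths from an edge list.
floyd_distances <- function(n, edges, weights) {
  W <- matrix(Inf, n, n)
  diag(W) <- 0
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    W[i, j] <- min(W[i, j], weights[e])
    W[j, i] <- min(W[j, i], weights[e])
  }
  for (k in seq_len(n)) W <- pmin(W, outer(W[, k], W[k, ], "+"))
  W
}

# Brute-force radius-capped kNN edge set (symmetrized, unique i < j pairs).
brute_knn_edges <- function(xyz, k, cap) {
  n <- nrow(xyz)
  D <- as.matrix(stats::dist(xyz))
  pairs <- NULL
  for (i in seq_len(n)) {
    d <- D[i, ]; d[i] <- Inf
    ok <- which(d <= cap)
    nn <- ok[order(d[ok])][seq_len(min(k, length(ok)))]
    if (length(nn))
      pairs <- rbind(pairs, cbind(pmin(i, nn), pmax(i, nn)))
  }
  if (is.null(pairs)) return(matrix(integer(0), ncol = 2))
  unique(pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE])
}

make_seed <- function(idx, diameter, confidence = 1, centroid = c(0, 0, 0),
                      dir_index = 0L) {
  structure(list(idx = as.integer(idx), centroid = centroid,
                 confidence = confidence, diameter = diameter,
                 direction = view_direction(dir_index, 32L),
                 n_points = length(idx)),
            class = "stem_seed3d")
}
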