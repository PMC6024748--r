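test_that("the confidence filter is strictly greater-than", {
  dets <- lapply(c(0.89, 0.90, 0.91), function(cf)
    structure(list(box = box2d(0, 0, 1, 1), confidence = cf),
              class = "stem_detection"))
  kept <- filter_confidence(dets, 0.9)
  expect_equal(length(kept), 1L)
  expect_equal(kept[[1]]$confidence, 0.91)
  expect_equal(filter_confidence(list(), 0.9), list())
  expect_equal(length(filter_confidence(dets, 0)), 3L)
})

test_that("a detection maps back to the world points inside its 3D box", {
  # identity direction: a single point at the box centre is the sole seed
  world <- point_cloud(rbind(c(0.5, 0.008, 0.5), c(0.9, 0.008, 0.9)))
  win <- slice_window(c(0, 0, 0), depth_y = 0.016)
  det <- structure(list(box = box2d(124, 124, 126, 126), confidence = 0.95,
                        window = win),
                   class = "stem_detection")
  seed <- map_to_3d(det, win, world)
  expect_equal(seed$idx, 1L)
  expect_equal(seed$centroid, world$xyz[1, ])
  expect_equal(seed$diameter, 0.005)   # floored
  # empty box errors
  det2 <- det; det2$box <- box2d(0, 0, 2, 2)
  expect_error(map_to_3d(det2, win, world), "no world point")
})

test_that("box membership equals brute-force point-in-box after rotation", {
  world <- random_cloud(800, seed = 9)
  world$xyz[, 2] <- world$xyz[, 2] * 0.8
  dir <- view_direction(5L, 32L)
  win <- slice_window(c(0.1, 0.2, 0.05), depth_y = 0.3, direction = dir)
  det <- structure(list(box = box2d(30, 20, 120, 200), confidence = 1,
                        window = win),
                   class = "stem_detection")
  seed <- map_to_3d(det, win, world)
  # brute force: rotate explicitly with the rotation matrix about centroid
  ctr <- colMeans(world$xyz[, 1:2])
  a <- dir$angle
  rx <- ctr[1] + cos(a) * (world$xyz[, 1] - ctr[1]) -
    sin(a) * (world$xyz[, 2] - ctr[2])
  ry <- ctr[2] + sin(a) * (world$xyz[, 1] - ctr[1]) +
    cos(a) * (world$xyz[, 2] - ctr[2])
  o <- win$origin
  inside <- which(rx >= o[1] + 30 * 0.004 & rx < o[1] + 120 * 0.004 &
                    ry >= o[2] & ry < o[2] + 0.3 &
                    world$xyz[, 3] >= o[3] + 20 * 0.004 &
                    world$xyz[, 3] < o[3] + 200 * 0.004)
  expect_equal(seed$idx, inside)
  expect_equal(seed$centroid, colMeans(world$xyz[inside, , drop = FALSE]))
})

test_that("seed diameter recovers a synthetic cylinder's diameter", {
  spec <- field_spec("sparse", noise_sd = 0, dropout_rate = 0)
  tr <- plant_truth(1L, c(0.5, 0.5), 0.4, stem_diameter = 0.02)
  stem <- generate_plant(tr, spec, seed = 2, n_leaves = 0L)
  win <- slice_window(c(0, 0.49, 0), depth_y = 0.016)
  inwin <- stem$xyz[, 2] >= 0.49 & stem$xyz[, 2] < 0.506
  det <- structure(list(box = box2d(0, 0, 256, 256), confidence = 1,
                        window = win),
                   class = "stem_detection")
  seed <- map_to_3d(det, win, point_cloud(stem$xyz))
  expect_lt(abs(seed$diameter - 0.02), 0.004 + 1e-9)
})

test_that("direction fusion keeps the best detection per plant", {
  s1 <- make_seed(1L, 0.02, confidence = 0.95, centroid = c(0, 0, 0.1))
  s2 <- make_seed(2L, 0.02, confidence = 0.92, centroid = c(0.02, 0, 0.1))
  s3 <- make_seed(3L, 0.02, confidence = 0.93, centroid = c(0.5, 0, 0.1))
  fused <- fuse_directions(list(s1, s2, s3), merge_radius = 0.1)
  expect_equal(length(fused), 2L)
  expect_equal(sort(vapply(fused, `[[`, 1.0, "confidence")), c(0.93, 0.95))
  far <- fuse_directions(list(s1, s3), merge_radius = 0.1)
  expect_equal(length(far), 2L)
})

test_that("fusion grouping equals a single-linkage oracle and ignores input order", {
  set.seed(11)
  for (trial in 1:5) {
    n <- sample(5:20, 1)
    xy <- matrix(runif(2 * n, 0, 0.6), ncol = 2)
    seeds <- lapply(seq_len(n), function(i)
      make_seed(i, runif(1, 0.01, 0.03), confidence = runif(1),
                centroid = c(xy[i, ], 0.1), dir_index = sample(0:31, 1)))
    fused <- fuse_directions(seeds, merge_radius = 0.1)
    # oracle: connected components of the "within radius" graph
    adj <- as.matrix(dist(xy)) <= 0.1
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    expect_equal(length(fused), max(comp))
    # winner per component has that component's maximal confidence
    conf <- vapply(seeds, `[[`, 1.0, "confidence")
    best_by_comp <- sort(vapply(split(conf, comp), max, 1.0), method = "radix")
    expect_equal(sort(vapply(fused, `[[`, 1.0, "confidence"), method = "radix"),
                 unname(best_by_comp))
    # permutation invariance
    perm <- sample(n)
    fused2 <- fuse_directions(seeds[perm], merge_radius = 0.1)
    expect_equal(seeds_table(fused), seeds_table(fused2))
  }
})
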