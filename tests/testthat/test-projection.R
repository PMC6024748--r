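test_that("rotation honours the identities of a rotation about z", {
  pc <- random_cloud(100, seed = 1)
  expect_equal(rotate_cloud(pc, view_direction(0L))$xyz, pc$xyz)

  full <- rotate_cloud(pc, view_direction(31L, 32L))
  almost <- rotate_cloud(full, view_direction(1L, 32L))
  expect_lt(max(abs(almost$xyz - pc$xyz)), 1e-9)

  # quarter turn about the centroid (here the origin by symmetry)
  sym <- point_cloud(rbind(c(2, 0, 0.1), c(-2, 0, 0.1),
                           c(0, 2, 0.5), c(0, -2, 0.5)))
  q <- rotate_cloud(sym, view_direction(8L, 32L))   # pi/2
  expect_equal(q$xyz[1, 1:2], c(x = 0, y = 2), tolerance = 1e-12)
})

test_that("rotation preserves pairwise distances and z exactly", {
  pc <- random_cloud(60, seed = 2)
  for (v in c(3L, 17L, 29L)) {
    rot <- rotate_cloud(pc, view_direction(v, 32L))
    expect_identical(rot$xyz[, 3], pc$xyz[, 3])
    expect_lt(max(abs(dist(rot$xyz) - dist(pc$xyz))), 1e-9)
  }
})

test_that("slice windows partition the cloud with the expected stride", {
  set.seed(3)
  pc <- point_cloud(cbind(runif(400, 0, 0.5), runif(400, 0, 0.048 - 1e-9),
                          runif(400, 0, 0.5)))
  wins <- slice_windows(pc, field = 1.024, depth = 0.016)
  expect_equal(length(wins), 3L)   # one x column, three depth slabs
  expect_equal(length(slice_windows(point_cloud(matrix(numeric(0), ncol = 3)))),
               0L)
  # partition property on a bigger random cloud
  pc2 <- random_cloud(3000, seed = 4, extent = 3)
  wins2 <- slice_windows(pc2, field = 1.024, depth = 0.016)
  idx <- sort(unlist(lapply(wins2, `[[`, "idx")))
  expect_identical(idx, seq_len(3000L))
  for (w in wins2[c(1, length(wins2))]) {
    o <- w$window$origin
    p <- pc2$xyz[w$idx, , drop = FALSE]
    expect_true(all(p[, 1] >= o[1] & p[, 1] < o[1] + w$window$field_x))
    expect_true(all(p[, 2] >= o[2] & p[, 2] < o[2] + w$window$depth_y))
  }
})

test_that("rasterization encodes nearest-surface intensity per pixel", {
  win <- slice_window(c(0, 0, 0), depth_y = 0.016)
  empty <- rasterize(point_cloud(matrix(numeric(0), ncol = 3)), win)
  expect_true(all(empty$pixels == 0))
  expect_equal(dim(empty$pixels), c(256L, 256L))

  centre <- rasterize(point_cloud(matrix(c(0.512, 0, 0.512), 1)), win)
  expect_equal(centre$pixels[129, 129], 1)   # pixel (128, 128), 0-based
  expect_equal(sum(centre$pixels > 0), 1L)

  two <- rasterize(point_cloud(rbind(c(0.1, 0.012, 0.1), c(0.1, 0.004, 0.1))),
                   win)
  expect_equal(max(two$pixels), 0.75)        # 1 - 0.004/0.016
  expect_equal(sum(two$pixels > 0), 1L)

  # permutation invariance
  pc <- random_cloud(500, seed = 5)
  pc$xyz[, 2] <- pc$xyz[, 2] * 0.015
  win1 <- slice_window(c(0, 0, 0), depth_y = 0.016, field_x = 1.024,
                       field_z = 1.024)
  a <- rasterize(pc, win1)
  b <- rasterize(cloud_subset(pc, sample(n_points(pc))), win1)
  expect_identical(a$pixels, b$pixels)

  expect_error(rasterize(point_cloud(matrix(c(2, 0, 0), 1)), win),
               "outside window")
})

test_that("pixel to meter to pixel round trip is the identity on centres", {
  win <- slice_window(c(0.3, 0.1, -0.2), depth_y = 0.016)
  px <- c(0, 17, 128, 255)
  mx <- win$origin[1] + (px + 0.5) * 0.004
  expect_equal(floor((mx - win$origin[1]) / 0.004), px)
})

test_that("training samples carry stem boxes below a third of plant height", {
  tp <- two_plant_cloud()
  samples <- make_training_samples(tp$cloud, tp$truths, n_views = 4L)
  expect_equal(length(samples), 2L * 4L)
  for (s in samples) {
    tr <- tp$truths[[s$plant_id]]
    # stem box within plant box, boxes within image bounds
    expect_gte(s$stem_box$x_min, s$plant_box$x_min)
    expect_lte(s$stem_box$x_max, s$plant_box$x_max)
    expect_gte(s$stem_box$z_min, s$plant_box$z_min)
    expect_lte(s$stem_box$z_max, s$plant_box$z_max)
    expect_gte(s$plant_box$x_min, 0)
    expect_lte(s$plant_box$x_max, 256)
    expect_gte(s$plant_box$z_min, 0)
    expect_lte(s$plant_box$z_max, 256)
    expect_s3_class(s$image, "depth_image")
  }
  # brute-force stem box check in the rotated frame for one sample
  s <- samples[[5]]
  rot <- rotate_cloud(tp$cloud, s$direction)
  pxyz <- rot$xyz[tp$cloud$label == s$plant_id, , drop = FALSE]
  zb <- min(pxyz[, 3]); h <- max(pxyz[, 3]) - zb
  stem <- pxyz[pxyz[, 3] - zb < h / 3, , drop = FALSE]
  px <- floor((stem[, 1] - s$window$origin[1]) / 0.004)
  pz <- floor((stem[, 3] - s$window$origin[3]) / 0.004)
  expect_equal(s$stem_box$x_min, min(px))
  expect_equal(s$stem_box$x_max, max(px) + 1L)
  expect_equal(s$stem_box$z_min, min(pz))
  expect_equal(s$stem_box$z_max, max(pz) + 1L)
  # the height/3 rule in meters: a 0.30 m plant has stems below ~0.10 m
  expect_lt(max(stem[, 3] - zb), tp$truths[[s$plant_id]]$height / 3 + 0.01)
})

test_that("sample count is plants x views and skipping keeps images optional", {
  tp <- two_plant_cloud()
  light <- make_training_samples(tp$cloud, tp$truths, n_views = 3L,
                                 keep_images = FALSE)
  expect_equal(length(light), 6L)
  expect_null(light[[1]]$image)
})
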