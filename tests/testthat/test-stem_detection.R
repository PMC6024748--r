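test_that("iou matches hand-computed and degenerate cases", {
  a <- box2d(0, 0, 2, 2)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, box2d(5, 5, 6, 6)), 0)
  expect_equal(iou(a, box2d(1, 0, 3, 2)), 1 / 3)   # 2 px over 6 px
  expect_equal(iou(box2d(0, 0, 4, 4), box2d(2, 2, 6, 6)), 4 / 28)
})

test_that("iou equals the pixel-enumeration oracle for all small boxes", {
  # every box of width/height <= 8 inside a 12 x 12 pixel grid
  g <- expand.grid(w = 1:8, h = 1:8, x0 = 0:11, z0 = 0:11)
  g <- g[g$x0 + g$w <= 12 & g$z0 + g$h <= 12, ]
  nb <- nrow(g)
  mask <- matrix(FALSE, nb, 144)
  cell <- function(px, pz) pz * 12 + px + 1
  for (i in seq_len(nb)) {
    px <- g$x0[i] + seq_len(g$w[i]) - 1
    pz <- g$z0[i] + seq_len(g$h[i]) - 1
    mask[i, as.vector(outer(px, pz, cell))] <- TRUE
  }
  m <- mask * 1
  inter <- tcrossprod(m)                       # pixel-enumeration overlap
  area <- rowSums(m)
  oracle <- inter / (outer(area, area, "+") - inter)
  # closed-form iou, vectorized over all pairs
  x0 <- g$x0; x1 <- g$x0 + g$w; z0 <- g$z0; z1 <- g$z0 + g$h
  iw <- pmax(0, outer(x1, x1, pmin) - outer(x0, x0, pmax))
  ih <- pmax(0, outer(z1, z1, pmin) - outer(z0, z0, pmax))
  ivec <- iw * ih
  closed <- ivec / (outer(area, area, "+") - ivec)
  expect_equal(closed, oracle, tolerance = 1e-12)
  # and the iou() entry point agrees with the oracle on a random subsample
  set.seed(1)
  pick <- cbind(sample(nb, 400, TRUE), sample(nb, 400, TRUE))
  for (r in seq_len(nrow(pick))) {
    i <- pick[r, 1]; j <- pick[r, 2]
    bi <- box2d(g$x0[i], g$z0[i], g$x0[i] + g$w[i], g$z0[i] + g$h[i])
    bj <- box2d(g$x0[j], g$z0[j], g$x0[j] + g$w[j], g$z0[j] + g$h[j])
    expect_equal(iou(bi, bj), oracle[i, j])
    expect_equal(iou(bj, bi), oracle[i, j])    # symmetry
  }
})

test_that("anchor labelling follows the overlap rules with a max-IoU override", {
  gt <- box2d(10, 10, 20, 30)
  # single anchor with any positive overlap is foreground
  weak <- list(box2d(18, 25, 40, 60))
  lab <- label_anchors(weak, gt)
  expect_lt(lab$iou[1], 0.3)
  expect_equal(as.character(lab$label[1]), "foreground")

  # a perfect anchor has all-zero offsets
  lab2 <- label_anchors(list(gt), gt)
  expect_equal(unlist(lab2[1, c("dx", "dz", "dw", "dh")]),
               c(dx = 0, dz = 0, dw = 0, dh = 0))

  # IoU strata {~0.2, ~0.5, ~0.8} -> background / ignore / foreground
  anchors <- list(box2d(26, 10, 36, 30),    # far: low overlap
                  box2d(15, 10, 25, 30),    # half shifted: iou = 1/3 band
                  box2d(10, 12, 20, 32))    # nearly aligned: high
  ious <- vapply(anchors, iou, 1.0, b = gt)
  expect_true(ious[1] < 0.3 && ious[2] > 0.3 && ious[2] < 0.7 && ious[3] > 0.7)
  lab3 <- label_anchors(anchors, gt)
  expect_equal(as.character(lab3$label),
               c("background", "ignore", "foreground"))
  # exactly one class per anchor and the max-IoU anchor never background
  expect_false(any(is.na(lab3$label)))
  expect_equal(as.character(lab3$label[which.max(lab3$iou)]), "foreground")
})

test_that("anchor regression offsets invert to the ground-truth box", {
  gt <- box2d(12, 40, 18, 80)
  a <- box2d(10, 40, 20, 70)
  lab <- label_anchors(list(a), gt)   # sole anchor: foreground by max rule
  i <- 1
  aw <- 10; ah <- 30
  cx <- 15 + lab$dx[i] * aw; cz <- 55 + lab$dz[i] * ah
  w <- aw * exp(lab$dw[i]); h <- ah * exp(lab$dh[i])
  expect_equal(c(cx - w / 2, cz - h / 2, cx + w / 2, cz + h / 2),
               c(12, 40, 18, 80))
})

test_that("default anchor scheme yields 20 anchors of 4 areas x 5 ratios", {
  sh <- anchor_shapes(anchor_config())
  expect_equal(nrow(sh), 20L)
  expect_equal(sort(unique(sh$area)), c(1, 49, 196, 3481))
  expect_equal(sh$height / sh$width, sh$ratio, tolerance = 1e-12)
})

test_that("the baseline detector finds upright bars and rejects everything else", {
  expect_equal(detect_baseline(bar_image(0, 0, 0 + 1, 1) ), list())  # dot
  blank <- bar_image(10, 10, 1, 1); blank$pixels[] <- 0
  expect_equal(detect_baseline(blank), list())

  tall <- bar_image(100, 4, 3, 40)
  dets <- detect_baseline(tall)
  expect_equal(length(dets), 1L)
  expect_equal(unlist(dets[[1]]$box),
               c(x_min = 100, z_min = 4, x_max = 103, z_max = 44))
  expect_equal(dets[[1]]$confidence, 1)   # solid, elongation saturated

  flat <- bar_image(100, 4, 40, 3)
  expect_equal(detect_baseline(flat), list())

  # an elongated bar floating high above other content fails the bottom rule
  img <- bar_image(100, 200, 3, 40)
  img$pixels[1:5, 30:60] <- 0.5
  expect_equal(detect_baseline(img), list())
})

test_that("baseline detection is translation invariant up to cropping", {
  base <- detect_baseline(bar_image(60, 10, 4, 50))
  shifted <- detect_baseline(bar_image(90, 35, 4, 50))
  expect_equal(length(base), 1L)
  expect_equal(shifted[[1]]$box$x_min - base[[1]]$box$x_min, 30)
  expect_equal(shifted[[1]]$box$z_min - base[[1]]$box$z_min, 25)
  expect_equal(shifted[[1]]$confidence, base[[1]]$confidence)
})

test_that("detect dispatches on the backend and guards bad handles", {
  img <- bar_image(100, 4, 3, 40)
  expect_equal(detect(img, baseline_config()), detect_baseline(img))
  expect_error(detect(img, structure(list(), class = "learned_backend")),
               "not been trained")
  expect_error(detect(img, list()), "unknown detector backend")
})

test_that("training the learned backend validates input, then reports the missing engine", {
  expect_error(train_learned_backend(list()), "0 samples")
  expect_error(
    train_learned_backend(list(1), engine = "definitely_not_installed"),
    "optional 'definitely_not_installed' engine")
})
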