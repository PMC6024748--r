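test_that("exact label agreement yields all true positives", {
  ref <- c(0L, 1L, 1L, 2L, 2L, 3L)
  m <- match_plants(ref, ref)
  expect_equal(unclass(m$counts)[c("tp", "fp", "fn")],
               list(tp = 3L, fp = 0L, fn = 0L))
  empty <- match_plants(rep(0L, 6), ref)
  expect_equal(empty$counts$tp, 0L)
  expect_equal(empty$counts$fn, 3L)
  expect_equal(empty$counts$fp, 0L)
  expect_error(match_plants(1:3, 1:4), "different point sets")
})

test_that("matching counts equal an exhaustive-assignment oracle", {
  # exhaustive search over one-to-one assignments, maximizing total
  # overlap; TP counts the assigned pairs meeting the coverage rule
  oracle_counts <- function(pred, ref, coverage = 0.5) {
    pred_ids <- setdiff(unique(pred), 0L); ref_ids <- setdiff(unique(ref), 0L)
    ov <- outer(pred_ids, ref_ids,
                Vectorize(function(p, r) sum(pred == p & ref == r)))
    refsz <- vapply(ref_ids, function(r) sum(ref == r), 1L)
    best <- list(total = -1, tp = 0)
    recurse <- function(i, used, total, tp) {
      if (i > length(pred_ids)) {
        if (total > best$total) best <<- list(total = total, tp = tp)
        return()
      }
      recurse(i + 1, used, total, tp)
      for (j in seq_along(ref_ids)) if (!used[j] && ov[i, j] > 0) {
        used[j] <- TRUE
        recurse(i + 1, used, total + ov[i, j],
                tp + (ov[i, j] >= coverage * refsz[j]))
        used[j] <- FALSE
      }
    }
    recurse(1L, rep(FALSE, length(ref_ids)), 0, 0)
    best$tp
  }
  set.seed(21)
  for (trial in 1:8) {
    n_pl <- sample(2:4, 1)
    ref <- rep(seq_len(n_pl), each = 30)
    pred <- ref
    flip <- sample(length(pred), round(0.1 * length(pred)))
    pred[flip] <- sample(0:n_pl, length(flip), replace = TRUE)
    m <- match_plants(pred, ref)
    # on mildly perturbed labels greedy matching is optimal: every ref
    # plant keeps a dominant overlap with its own prediction
    expect_equal(m$counts$tp, oracle_counts(pred, ref))
    expect_equal(m$counts$tp + m$counts$fn, length(unique(ref[ref > 0])))
    expect_equal(m$counts$tp + m$counts$fp,
                 length(setdiff(unique(pred), 0L)))
  }
})

test_that("r, p and F reproduce the published worked examples", {
  # overall row: TP 206, FP 12, FN 15 -> 0.93 / 0.94 / 0.94
  s <- prf(confusion_counts(206, 12, 15))
  expect_equal(round(unname(s), 2), c(0.93, 0.94, 0.94))
  # moderate row: TP 66, FP 2, FN 5 -> 0.93 / 0.97 / 0.95
  s2 <- prf(confusion_counts(66, 2, 5))
  expect_equal(round(unname(s2), 2), c(0.93, 0.97, 0.95))
  # perfect segmentation
  expect_equal(unname(prf(confusion_counts(10, 0, 0))), c(1, 1, 1))
  expect_error(prf(confusion_counts(0, 0, 5)), "undefined")
  expect_error(prf(confusion_counts(0, 0, 0)), "undefined")
})

test_that("F is the harmonic mean, between min and max of r and p", {
  set.seed(31)
  for (i in 1:25) {
    tp <- sample(1:100, 1); fp <- sample(0:30, 1); fn <- sample(0:30, 1)
    s <- prf(confusion_counts(tp, fp, fn))
    expect_equal(s[["f"]], 2 / (1 / s[["r"]] + 1 / s[["p"]]))
    expect_gte(s[["f"]], min(s[["r"]], s[["p"]]) - 1e-12)
    expect_lte(s[["f"]], max(s[["r"]], s[["p"]]) + 1e-12)
  }
})

test_that("plant height is the vertical extent of the surviving points", {
  spec <- field_spec("sparse", noise_sd = 0, dropout_rate = 0,
                     ground_relief_amp = 0)
  tr <- plant_truth(1L, c(0.5, 0.5), 0.30, 0.02)
  pc <- generate_plant(tr, spec, seed = 4)
  flat <- fit_ground(point_cloud(cbind(runif(100), runif(100), 0)))
  expect_lt(abs(plant_height(pc$xyz, flat) - 0.30), 1e-6)
  # cutting the base at 0.1 m shortens the measured plant by ~0.1 m
  # (up to the surface sampling step: the lowest surviving sample sits
  # just above the cut)
  cut <- pc$xyz[pc$xyz[, 3] >= 0.1, , drop = FALSE]
  expect_lt(abs(plant_height(cut, flat) - 0.20), spec$point_spacing)
  # brute-force equality on random sets
  rc <- random_cloud(300, seed = 41)
  m <- fit_ground(rc)
  nz <- rc$xyz[, 3] - ground_at(m, rc$xyz)
  expect_equal(plant_height(rc$xyz, m), max(nz) - max(0, min(nz)))
  expect_error(plant_height(matrix(numeric(0), ncol = 3), flat), "empty")
})

test_that("height regression matches the closed-form least-squares fit", {
  ref <- c(0.2, 0.3, 0.4, 0.55)
  expect_equal(unname(height_regression(ref, ref)), c(1, 0, 0))
  off <- height_regression(ref - 0.02, ref)
  expect_equal(unname(off), c(1, 0, -0.02))
  set.seed(51)
  for (i in 1:10) {
    x <- runif(20, 0.1, 0.7); y <- 0.9 * x + rnorm(20, 0, 0.02)
    got <- height_regression(y, x)
    b <- cov(x, y) / var(x); a <- mean(y) - b * mean(x)
    res <- y - (a + b * x)
    expect_equal(got[["r2"]], 1 - sum(res^2) / sum((y - mean(y))^2))
    expect_equal(got[["rmse"]], sqrt(mean(res^2)))
    expect_equal(got[["mean_bias"]], mean(y - x))
  }
  expect_error(height_regression(c(1, 2), c(3, 3)), "degenerate")
})
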