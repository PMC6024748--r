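#' Match predicted plants to reference plants
#'
#' Greedy one-to-one matching by descending point overlap: predicted and
#' reference plants share the same point index space; each (pred, ref)
#' pair's overlap is its shared point count; pairs are accepted in
#' decreasing overlap order, each plant used at most once, and an accepted
#' pair counts as a true positive when the overlap covers at least
#' `coverage` (default 50%) of the reference plant's points. Unmatched
#' reference plants are false negatives; unmatched predictions false
#' positives.
#'
#' @param pred_label integer vector of predicted per-point labels (0 =
#'   unassigned), or a `segmentation_result`.
#' @param ref_label integer vector of reference per-point labels (0 =
#'   ground/none) of the same length.
#' @param coverage TP coverage threshold (default 0.5).
#' @return A list: `counts` (`tp`, `fp`, `fn`), `pairs` (data.frame of
#'   matched pred/ref ids with overlap and coverage).
#' @export
match_plants <- function(pred_label, ref_label, coverage = 0.5) {
  if (inherits(pred_label, "segmentation_result"))
    pred_label <- pred_label$label
  if (inherits(ref_label, "stalk_cloud")) ref_label <- ref_label$label
  if (length(pred_label) != length(ref_label))
    stop("predicted and reference labels index different point sets (",
         length(pred_label), " != ", length(ref_label), ")")
  pred_ids <- setdiff(sort(unique(pred_label)), 0L)
  ref_ids <- setdiff(sort(unique(ref_label)), 0L)
  ref_size <- table(factor(ref_label[ref_label != 0L], ref_ids))
  both <- pred_label != 0L & ref_label != 0L
  ov <- if (length(pred_ids) && length(ref_ids) && any(both)) {
    tab <- as.data.frame(table(pred = factor(pred_label[both], pred_ids),
                               ref = factor(ref_label[both], ref_ids)),
                         stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0L, , drop = FALSE]
    tab[order(-tab$Freq, tab$pred, tab$ref), , drop = FALSE]
  } else data.frame(pred = character(), ref = character(), Freq = integer())
  used_pred <- character(); used_ref <- character()
  pairs <- list()
  for (r in seq_len(nrow(ov))) {
    if (ov$pred[r] %in% used_pred || ov$ref[r] %in% used_ref) next
    used_pred <- c(used_pred, ov$pred[r]); used_ref <- c(used_ref, ov$ref[r])
    cov <- ov$Freq[r] / as.integer(ref_size[ov$ref[r]])
    if (cov >= coverage)
      pairs[[length(pairs) + 1L]] <- data.frame(
        pred = as.integer(ov$pred[r]), ref = as.integer(ov$ref[r]),
        overlap = ov$Freq[r], coverage = cov)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
  else data.frame(pred = integer(), ref = integer(),
                  overlap = integer(), coverage = numeric())
  tp <- nrow(pairs)
  list(counts = confusion_counts(tp = tp,
                                 fp = length(pred_ids) - tp,
                                 fn = length(ref_ids) - tp),
       pairs = pairs)
}

#' Plant-level confusion counts
#' @param tp,fp,fn non-negative integer counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn)), class = "confusion_counts")
}

#' Recall, precision and F-score from confusion counts
#'
#' Recall `TP/(TP+FN)`, precision `TP/(TP+FP)` and F-score `2rp/(r+p)`,
#' with F computed from the unrounded recall and precision. Values are
#' reported to 2 decimals in print methods and reports; the returned
#' numbers are unrounded.
#'
#' @param counts a [confusion_counts()] (or list with tp/fp/fn).
#' @return Named numeric vector `c(r, p, f)`.
#' @export
prf <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (tp + fn == 0L && tp + fp == 0L)
    stop("r/p/F undefined: no reference and no predicted plants")
  if (tp + fn == 0L || tp + fp == 0L)
    stop("r/p/F undefined: empty ",
         if (tp + fn == 0L) "reference" else "prediction", " set")
  r <- tp / (tp + fn)
  p <- tp / (tp + fp)
  f <- if (r + p == 0) 0 else 2 * r * p / (r + p)
  c(r = r, p = p, f = f)
}

#' Plant height from a point set
#'
#' Height of one plant as the vertical extent of its points after ground
#' normalization: max normalized z minus the plant's own lowest normalized
#' z (floored at 0). Defined this way, removing stem-base points with the
#' ground threshold shortens the measured plant, reproducing the
#' systematic underestimation a fixed ground cut induces.
#'
#' @param points n x 3 coordinate matrix (or a [point_cloud()]) of one
#'   plant's points; must be nonempty.
#' @param ground a [fit_ground()] model.
#' @return Height in m.
#' @export
plant_height <- function(points, ground) {
  if (inherits(points, "stalk_cloud")) points <- points$xyz
  if (is.null(dim(points)) || nrow(points) == 0L)
    stop("cannot measure the height of an empty point set")
  nz <- points[, 3] - ground_at(ground, points)
  max(nz) - max(0, min(nz))
}

#' Regress automatic against reference heights
#'
#' Least-squares fit `auto ~ ref`; reports the coefficient of
#' determination of the fit, the root-mean-squared residual, and the mean
#' bias `mean(auto - ref)` (the ground-cut underestimation shows up here
#' as a negative bias, separate from the fit quality).
#'
#' @param auto,ref numeric vectors of heights in m (>= 2 pairs), or a
#'   2-column matrix/data.frame in `auto`.
#' @return Named numeric vector `c(r2, rmse, mean_bias)`.
#' @export
height_regression <- function(auto, ref = NULL) {
  if (is.null(ref)) { ref <- auto[, 2]; auto <- auto[, 1] }
  stopifnot(length(auto) == length(ref), length(auto) >= 2L)
  if (stats::sd(ref) == 0)
    stop("degenerate height regression: reference heights are constant")
  fit <- stats::lm(auto ~ ref)
  res <- stats::residuals(fit)
  tss <- sum((auto - mean(auto))^2)
  c(r2 = if (tss > 0) 1 - sum(res^2) / tss else 1,
    rmse = sqrt(mean(res^2)),
    mean_bias = mean(auto - ref))
}

#' Evaluate a segmentation against reference labels
#'
#' Full plant-level report: confusion counts, r/p/F, and for the matched
#' (true-positive) plants a height regression of automatically measured
#' against reference heights.
#'
#' @param pred a `segmentation_result` (labels over the ground-removed
#'   cloud's points).
#' @param ref_label reference labels over the same points.
#' @param auto_heights,ref_heights optional named/indexed numeric vectors:
#'   heights of predicted plants (by seed id) and reference plants (by
#'   plant id). When both are given, matched pairs are regressed.
#' @return An object of class `eval_report` with elements `counts`, `r`,
#'   `p`, `f`, `pairs`, `height_pairs`, `r2`, `rmse`, `mean_bias` (the
#'   last three NA when heights are not supplied).
#' @export
evaluate_segmentation <- function(pred, ref_label,
                                  auto_heights = NULL, ref_heights = NULL) {
  m <- match_plants(pred, ref_label)
  s <- prf(m$counts)
  hp <- NULL; reg <- c(r2 = NA_real_, rmse = NA_real_, mean_bias = NA_real_)
  if (!is.null(auto_heights) && !is.null(ref_heights) && nrow(m$pairs) >= 2L) {
    pick <- function(v, id)     # by name when named, else by position = id
      if (!is.null(names(v))) unname(v[as.character(id)]) else v[id]
    hp <- data.frame(auto = pick(auto_heights, m$pairs$pred),
                     ref = pick(ref_heights, m$pairs$ref))
    reg <- height_regression(hp$auto, hp$ref)
  }
  structure(list(counts = m$counts, r = s[["r"]], p = s[["p"]], f = s[["f"]],
                 pairs = m$pairs, height_pairs = hp,
                 r2 = reg[["r2"]], rmse = reg[["rmse"]],
                 mean_bias = reg[["mean_bias"]]),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> TP %d  FP %d  FN %d\n",
              x$counts$tp, x$counts$fp, x$counts$fn))
  cat(sprintf("  r %.2f  p %.2f  F %.2f\n", x$r, x$p, x$f))
  if (!is.na(x$r2))
    cat(sprintf("  height: R2 %.2f  RMSE %.3f m  bias %+.3f m (n = %d)\n",
                x$r2, x$rmse, x$mean_bias, nrow(x$height_pairs)))
  invisible(x)
}
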