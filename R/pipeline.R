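#' Pipeline configuration
#'
#' Aggregates every constant of the segmentation method. Defaults follow
#' the method's published operating point: 32 viewing directions, a
#' 1.024 m x 1.024 m image field, 0.016 m test slab depth (0.256 m for
#' training ROIs), 0.004 m pixels, a strict 90% detection-confidence
#' filter, 0.1 m seed merge radius, 0.1 m ground threshold on 0.25 m
#' cells, a k = 10 / 0.05 m neighbour graph, and the z < height/3 stem
#' labelling fraction.
#'
#' @param n_views number of viewing directions.
#' @param field image field size in m.
#' @param test_depth,train_depth slab depths in m.
#' @param pixel_size m per pixel.
#' @param min_conf detection confidence filter (strictly greater than).
#' @param merge_radius seed fusion radius in m.
#' @param ground_threshold,ground_cell ground filter parameters in m.
#' @param k,radius_cap neighbour-graph parameters.
#' @param stem_fraction stem labelling height fraction.
#' @param backend detector backend: `"baseline"` or `"learned"`.
#' @param min_window_points windows with fewer points are not rasterized
#'   (performance knob; well below any detectable stem's point count).
#' @param rng_seed integer seed for synthetic generation steps.
#' @return An object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(n_views = 32L, field = 1.024,
                            test_depth = 0.016, train_depth = 0.256,
                            pixel_size = 0.004, min_conf = 0.9,
                            merge_radius = 0.1, ground_threshold = 0.1,
                            ground_cell = 0.25, k = 10L, radius_cap = 0.05,
                            stem_fraction = 1 / 3, backend = "baseline",
                            min_window_points = 30L, rng_seed = 1L) {
  cfg <- list(n_views = as.integer(n_views), field = field,
              test_depth = test_depth, train_depth = train_depth,
              pixel_size = pixel_size, min_conf = min_conf,
              merge_radius = merge_radius,
              ground_threshold = ground_threshold, ground_cell = ground_cell,
              k = as.integer(k), radius_cap = radius_cap,
              stem_fraction = stem_fraction, backend = backend,
              min_window_points = as.integer(min_window_points),
              rng_seed = as.integer(rng_seed))
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  num_pos <- c("field", "test_depth", "train_depth", "pixel_size",
               "merge_radius", "ground_threshold", "ground_cell",
               "radius_cap")
  for (f in num_pos)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop("config field '", f, "' must be positive")
  stopifnot(cfg$n_views >= 1L, cfg$k >= 1L,
            cfg$min_conf >= 0, cfg$min_conf <= 1,
            cfg$stem_fraction > 0, cfg$stem_fraction < 1,
            cfg$backend %in% c("baseline", "learned"))
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML file holds exactly the fields of [pipeline_config()]; missing
#' fields take their defaults, so a partial file overrides selectively.
#'
#' @param path YAML file.
#' @return [read_config()]: a `pipeline_config`; [write_config()]: `path`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param config a [pipeline_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

# Detect stems over all directions; returns a list of stem_seed3d.
detect_seeds <- function(cloud, config, detector = baseline_config()) {
  seeds <- list()
  per_dir <- integer(config$n_views)
  for (v in seq_len(config$n_views) - 1L) {
    dir <- view_direction(v, config$n_views)
    rot <- rotate_cloud(cloud, dir)
    wins <- slice_windows(rot, field = config$field,
                          depth = config$test_depth, direction = dir)
    for (w in wins) {
      if (length(w$idx) < config$min_window_points) next
      img <- rasterize(cloud_subset(rot, w$idx), w$window,
                       pixel_size = config$pixel_size)
      dets <- filter_confidence(detect(img, detector), config$min_conf)
      for (d in dets) {
        seed <- tryCatch(
          map_to_3d(d, w$window, cloud, pixel_size = config$pixel_size,
                    rot = rot),
          error = function(e) NULL)
        if (!is.null(seed)) seeds[[length(seeds) + 1L]] <- seed
      }
    }
    per_dir[v + 1L] <- length(seeds)
  }
  attr(seeds, "cumulative_per_direction") <- per_dir
  seeds
}

#' Run the full segmentation pipeline
#'
#' Ground filtering, multi-directional slicing and depth-image stem
#' detection, confidence filtering, 2D-to-3D seed mapping, best-confidence
#' fusion across directions, comparative shortest-path region growing, and
#' per-plant height extraction. When the input cloud carries reference
#' plant labels, a plant-level evaluation (r/p/F and height regression) is
#' produced as well.
#'
#' @param cloud a [point_cloud()] in the world frame (labels optional).
#' @param config a [pipeline_config()].
#' @param truths optional list of [plant_truth()]; when supplied, reference
#'   heights come from the truths instead of the labelled points.
#' @param artifact_dir optional directory; when given, stage outputs
#'   (seeds, labels, report) are persisted there as CSV/JSON.
#' @param verbose print per-stage progress.
#' @return A list of class `pipeline_result`: `segmentation`
#'   (`segmentation_result` over the ground-removed cloud), `kept_idx`
#'   (indices of those points in the input cloud), `seeds`, `ground`
#'   (model), `heights` (per-plant data.frame), `report` (an
#'   `eval_report` or NULL), `config`.
#' @export
run_pipeline <- function(cloud, config = pipeline_config(), truths = NULL,
                         artifact_dir = NULL, verbose = FALSE) {
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  stopifnot(inherits(cloud, "stalk_cloud"))
  validate_config(config)

  ground <- fit_ground(cloud, cell_size = config$ground_cell)
  gf <- remove_ground(cloud, ground, threshold = config$ground_threshold)
  work <- gf$cloud
  say("ground filter: removed %d of %d points", gf$removed, n_points(cloud))
  if (n_points(work) == 0L)
    stop("no stems detected: every point was removed as ground")

  detector <- if (config$backend == "baseline") baseline_config()
  else stop("learned backend requested but no trained model is configured")
  raw_seeds <- detect_seeds(point_cloud(work$xyz), config, detector)
  say("detection: %d raw seeds over %d directions", length(raw_seeds),
      config$n_views)
  if (length(raw_seeds) == 0L)
    stop("no stems detected: no detection passed the ",
         sprintf("%.0f%%", 100 * config$min_conf), " confidence filter")
  seeds <- fuse_directions(raw_seeds, merge_radius = config$merge_radius)
  say("fusion: %d seeds after merging within %.2f m", length(seeds),
      config$merge_radius)

  seg <- segment(work, seeds, k = config$k, radius_cap = config$radius_cap)
  say("segmentation: %d of %d points assigned", sum(seg$label > 0L),
      n_points(work))

  heights <- data.frame(
    plant = seq_along(seeds),
    height = vapply(seq_along(seeds), function(s) {
      idx <- seg$label == s
      if (!any(idx)) return(NA_real_)
      plant_height(work$xyz[idx, , drop = FALSE], ground)
    }, 1.0),
    n_points = as.integer(tabulate(seg$label, length(seeds))))

  report <- NULL
  if (!is.null(cloud$label) && any(cloud$label > 0L)) {
    ref_label <- cloud$label[gf$kept_idx]
    ref_ids <- setdiff(sort(unique(cloud$label)), 0L)
    ref_heights <- if (!is.null(truths)) {
      stats::setNames(vapply(truths, `[[`, 1.0, "height"),
                      vapply(truths, `[[`, 1L, "plant_id"))
    } else {
      stats::setNames(vapply(ref_ids, function(id)
        plant_height(cloud$xyz[cloud$label == id, , drop = FALSE], ground),
        1.0), ref_ids)
    }
    auto_heights <- stats::setNames(heights$height, heights$plant)
    report <- evaluate_segmentation(seg, ref_label,
                                    auto_heights = auto_heights,
                                    ref_heights = ref_heights)
  }

  res <- structure(list(segmentation = seg, kept_idx = gf$kept_idx,
                        seeds = seeds, ground = ground, heights = heights,
                        report = report, config = config,
                        elapsed = as.numeric(difftime(Sys.time(), t0,
                                                      units = "secs"))),
                   class = "pipeline_result")
  if (!is.null(artifact_dir)) persist_artifacts(res, work, artifact_dir)
  res
}

persist_artifacts <- function(res, work, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(seeds_table(res$seeds),
                   file.path(dir, "seeds.csv"), row.names = FALSE)
  utils::write.csv(res$heights, file.path(dir, "heights.csv"),
                   row.names = FALSE)
  out <- point_cloud(work$xyz, label = res$segmentation$label)
  write_cloud(out, file.path(dir, "segmented.ply"))
  if (!is.null(res$report))
    jsonlite::write_json(
      list(tp = res$report$counts$tp, fp = res$report$counts$fp,
           fn = res$report$counts$fn,
           r = round(res$report$r, 2), p = round(res$report$p, 2),
           f = round(res$report$f, 2),
           height_r2 = res$report$r2, height_rmse = res$report$rmse,
           height_bias = res$report$mean_bias),
      file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d plants from %d points (%.1f s)\n",
              length(x$seeds), length(x$segmentation$label), x$elapsed))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
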