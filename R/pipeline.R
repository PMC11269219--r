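# End-to-end runs tying the stages together: simulate -> merge -> edges ->
# lengths -> tracks -> reports. These back the command-line interface in
# inst/cli/radicle.R; data goes to files, log messages to stderr.

#' Default run configuration
#'
#' Calibration defaults match the standard tray setup: a 25 cm x 25 cm
#' acrylic frame imaged at 1500 x 1500 px on a 6 x 6 seed grid.
#'
#' @param ... named overrides of the defaults.
#' @return a validated `run_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    actual_length_cm = 25,
    side_pixels = 1500L,
    rows = 6L, cols = 6L,
    canny = list(sigma = 1.4, kernel_size = 5L, low = 50, high = 150),
    amplify = list(offset = 1, scale = 2),
    simulate = list(n_frames = 3L, min_length_px = 60, max_length_px = 200,
                    thickness_px = 3L),
    seed = 1L,
    in_dir = NULL, out_dir = ".",
    pred_csv = NULL, truth_csv = NULL
  )
  over <- list(...)
  cfg[names(over)] <- over
  validate_config(cfg)
}

#' @rdname default_config
#' @param config a config list.
#' @export
validate_config <- function(config) {
  stopifnot(config$actual_length_cm > 0, config$side_pixels > 0,
            config$rows >= 1, config$cols >= 1)
  canny_params(config$canny$sigma, config$canny$kernel_size,
               config$canny$low, config$canny$high)
  stopifnot(config$simulate$n_frames >= 1,
            config$simulate$min_length_px > 0,
            config$simulate$max_length_px >= config$simulate$min_length_px,
            config$simulate$thickness_px >= 1)
  structure(config, class = "run_config")
}

#' Read / write a run configuration as JSON
#'
#' @param path JSON file path.
#' @export
read_config <- function(path) {
  validate_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_config
#' @param config a `run_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @keywords internal
#' @noRd
cfg_canny <- function(config) {
  canny_params(config$canny$sigma, config$canny$kernel_size,
               config$canny$low, config$canny$high)
}

#' @keywords internal
#' @noRd
cfg_cal <- function(config) {
  calibration_ratio(config$actual_length_cm, config$side_pixels)
}

#' @keywords internal
#' @noRd
log_msg <- function(...) message("[radiclemetry] ", sprintf(...))

#' Simulate a germinating tray time series to disk
#'
#' Draws one random radicle per grid cell, grows each linearly from half its
#' target length to the target across the frames, and writes per-frame
#' instance masks (`frame_XX/mask_YY.png`), composites
#' (`composite_XX.png`) and a ground-truth table `ground_truth.csv`
#' (frame, grid_row, grid_col, true_length_px, true_length_cm).
#'
#' @param config a `run_config`; uses `simulate`, layout, calibration and
#'   `seed` entries. Deterministic given the config.
#' @return the ground-truth data.frame, invisibly.
#' @export
run_simulate <- function(config = default_config()) {
  config <- validate_config(config)
  sim <- config$simulate
  size <- c(config$side_pixels, config$side_pixels)
  cal <- cfg_cal(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  cells <- expand.grid(row = seq_len(config$rows), col = seq_len(config$cols))
  lengths <- withr::with_seed(config$seed, {
    stats::runif(nrow(cells), sim$min_length_px, sim$max_length_px)
  })
  specs <- lapply(seq_len(nrow(cells)), function(i) {
    random_radicle_spec(c(cells$row[i], cells$col[i]), config$rows,
                        config$cols, size, lengths[i], sim$thickness_px,
                        rng_seed = config$seed + i)
  })
  truth <- data.frame()
  for (k in seq_len(sim$n_frames)) {
    fdir <- file.path(config$out_dir, sprintf("frame_%02d", k))
    dir.create(fdir, showWarnings = FALSE)
    frac <- if (sim$n_frames == 1L) 1 else 0.5 + 0.5 * (k - 1) / (sim$n_frames - 1)
    composite <- matrix(30L, size[1], size[2])
    for (i in seq_along(specs)) {
      dense <- dense_centerline(specs[[i]]$centerline_control_points)
      pts <- truncate_centerline(dense, frac * max(dense$cumlen))
      mask <- render_centerline_mask(pts, sim$thickness_px, size)
      composite[mask == 1L] <- 230L
      write_mask_png(mask * 255L, file.path(fdir, sprintf("mask_%02d.png", i)))
      truth <- rbind(truth, data.frame(
        frame = k, grid_row = cells$row[i], grid_col = cells$col[i],
        true_length_px = polyline_length(pts),
        true_length_cm = polyline_length(pts) * cal$R))
    }
    png::writePNG(composite / 255,
                  file.path(config$out_dir, sprintf("composite_%02d.png", k)))
    log_msg("frame %d: %d masks written to %s", k, length(specs), fdir)
  }
  utils::write.csv(truth, file.path(config$out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(truth)
}

#' @keywords internal
#' @noRd
measure_mask_dir <- function(dir, config) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  size <- c(config$side_pixels, config$side_pixels)
  masks <- lapply(files, function(f) read_mask_png(f)$grid / 255L)
  merged <- merge_masks(instance_mask_set(masks, size))
  edges <- canny(merged$grid, cfg_canny(config))
  list(merged = merged, edges = edges,
       measurements = measure_contours(edges, cfg_cal(config)))
}

#' Measure radicle lengths from a directory of instance masks
#'
#' Pipeline for one image: merge the per-instance masks in `config$in_dir`,
#' write the merged binary image (`in.png`), run the Canny chain, label and
#' measure contours with the half-perimeter rule, and write
#' `measurements.csv` plus an annotated PNG. An empty input directory yields
#' an empty CSV and a warning, not an error.
#'
#' @param config a `run_config` with `in_dir` set.
#' @return the measurement data.frame, invisibly.
#' @export
run_measure <- function(config) {
  config <- validate_config(config)
  if (is.null(config$in_dir) || !dir.exists(config$in_dir)) {
    stop("run_measure: in_dir does not exist")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- measure_mask_dir(config$in_dir, config)
  if (nrow(res$measurements) == 0L) {
    warning("no contours found in ", config$in_dir)
  }
  write_mask_png(res$merged, dir = config$out_dir)
  ann <- annotate_lengths(res$merged$grid, res$measurements, cfg_cal(config))
  png::writePNG(ann / 255, file.path(config$out_dir, "annotated.png"))
  write_measurements_csv(res$measurements,
                         file.path(config$out_dir, "measurements.csv"),
                         image_id = basename(config$in_dir))
  log_msg("measure: %d contour(s), %d edge px",
          nrow(res$measurements), count_edge_pixels(res$edges))
  invisible(res$measurements)
}

#' Track per-seed growth across a frame series
#'
#' `config$in_dir` must contain one subdirectory of instance masks per frame
#' (sorted lexicographically; frame k is assigned timestamp k hours). Each
#' frame is merged and measured, measurements are associated with tray
#' cells, and growth curves are written: `tracks.csv`, `growth_rates.csv`
#' and `amplified.csv` (per-frame mean length and the amplified-average
#' series).
#'
#' @param config a `run_config` with `in_dir` set; needs >= 2 frames.
#' @return list of growth curves, invisibly.
#' @export
run_track <- function(config) {
  config <- validate_config(config)
  fdirs <- sort(list.dirs(config$in_dir, recursive = FALSE))
  if (length(fdirs) < 2L) stop("run_track: need at least 2 frame directories")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cal <- cfg_cal(config)
  frames <- lapply(seq_along(fdirs), function(k) {
    res <- measure_mask_dir(fdirs[k], config)
    log_msg("frame %d (%s): %d contour(s)", k, basename(fdirs[k]),
            nrow(res$measurements))
    list(time_h = k, measurements = res$measurements)
  })
  tracks <- associate_seeds(frames, c(config$rows, config$cols),
                            c(config$side_pixels, config$side_pixels))
  write_tracks_csv(tracks, cal, file.path(config$out_dir, "tracks.csv"))
  curves <- list()
  rates <- data.frame()
  for (tr in tracks) {
    if (sum(!is.na(tr$observations$sum_pixels)) < 2L) next
    gc <- growth_rates(tr, cal, config$amplify$offset, config$amplify$scale)
    curves[[length(curves) + 1L]] <- gc
    rates <- rbind(rates, data.frame(
      grid_row = gc$grid_cell[1], grid_col = gc$grid_cell[2],
      t_start = gc$times[-length(gc$times)], t_end = gc$times[-1],
      rate_cm_per_h = gc$interval_rates))
  }
  utils::write.csv(rates, file.path(config$out_dir, "growth_rates.csv"),
                   row.names = FALSE)
  # per-frame mean length over tracked seeds, plus the amplified series
  times <- vapply(frames, function(f) f$time_h, numeric(1))
  mean_len <- vapply(seq_along(times), function(k) {
    lens <- vapply(tracks, function(tr) {
      sp <- tr$observations$sum_pixels[k]
      if (is.na(sp)) NA_real_ else measure_radicle(sp, cal)
    }, numeric(1))
    mean(lens, na.rm = TRUE)
  }, numeric(1))
  utils::write.csv(
    data.frame(timestamp_h = times, mean_length_cm = mean_len,
               amplified = amplify_average(mean_len, config$amplify$offset,
                                           config$amplify$scale)),
    file.path(config$out_dir, "amplified.csv"), row.names = FALSE)
  invisible(curves)
}

#' Evaluate detections against ground truth from CSV
#'
#' Reads predictions (`config$pred_csv`) and truths (`config$truth_csv`)
#' with columns `image_id, class_id, x_min, y_min, x_max, y_max` (plus
#' `confidence` for predictions), computes [map_range()] per image and
#' averages, and writes `eval.json`.
#'
#' @param config a `run_config` with `pred_csv` and `truth_csv` set.
#' @return the summary list, invisibly.
#' @export
run_eval <- function(config) {
  config <- validate_config(config)
  preds <- utils::read.csv(config$pred_csv)
  truths <- utils::read.csv(config$truth_csv)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- unique(truths$image_id)
  results <- lapply(ids, function(id) {
    map_range(preds[preds$image_id == id, , drop = FALSE],
              truths[truths$image_id == id, , drop = FALSE])
  })
  summary <- list(
    map50 = mean(vapply(results, function(r) r$map50, numeric(1))),
    map50_95 = mean(vapply(results, function(r) r$map50_95, numeric(1))),
    per_threshold_ap = Reduce(`+`, lapply(results, function(r) r$per_threshold_ap)) /
      length(results),
    n_images = length(ids))
  jsonlite::write_json(summary, file.path(config$out_dir, "eval.json"),
                       auto_unbox = TRUE, digits = NA)
  log_msg("eval: mAP50 %.3f, mAP50-95 %.3f over %d image(s)",
          summary$map50, summary$map50_95, summary$n_images)
  invisible(summary)
}
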