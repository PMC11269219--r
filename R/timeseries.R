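# Full-time-sequence tracking of per-seed radicle measurements on a fixed
# tray grid, interval growth rates, and the amplified-average visualization
# transform.

#' Associate contour measurements with tray cells over time
#'
#' Seeds sit at fixed positions in an `n_rows x n_cols` tray, so tracking is
#' by grid cell rather than nearest-neighbour matching: the image is
#' partitioned into equal cells and each measurement is assigned to the cell
#' containing its centroid. When several contours land in one cell in one
#' frame, the largest (`sum_pixels`) is kept and the others are recorded in
#' the `dropped` attribute. Cells without a measurement in a frame get an
#' `NA` observation (missing, not an error).
#'
#' @param frames list of frames, each `list(time_h, measurements)` where
#'   `measurements` is a [label_contours()]-style data.frame.
#' @param layout `c(n_rows, n_cols)`.
#' @param image_size `c(height, width)` px.
#' @return list of `seed_track` objects (one per grid cell, row-major),
#'   each with `grid_cell` and an `observations` data.frame
#'   (time_h, contour_id, sum_pixels; NA where missing).
#' @export
associate_seeds <- function(frames, layout, image_size) {
  n_rows <- layout[1]; n_cols <- layout[2]
  stopifnot(n_rows >= 1, n_cols >= 1)
  h <- image_size[1]; w <- image_size[2]
  times <- vapply(frames, function(f) f$time_h, numeric(1))
  if (is.unsorted(times, strictly = TRUE)) stop("frame times must be strictly increasing")

  obs <- array(NA_real_, dim = c(n_rows, n_cols, length(frames), 2),
               dimnames = list(NULL, NULL, NULL, c("contour_id", "sum_pixels")))
  dropped <- data.frame(time_h = numeric(), grid_row = integer(),
                        grid_col = integer(), contour_id = integer(),
                        sum_pixels = integer())
  for (k in seq_along(frames)) {
    m <- frames[[k]]$measurements
    if (is.null(m) || nrow(m) == 0L) next
    if (any(m$centroid_row < 0 | m$centroid_row > h |
            m$centroid_col < 0 | m$centroid_col > w)) {
      stop("measurement centroid outside image")
    }
    gr <- pmin(n_rows, floor((m$centroid_row - 0.5) / (h / n_rows)) + 1L)
    gc <- pmin(n_cols, floor((m$centroid_col - 0.5) / (w / n_cols)) + 1L)
    for (i in order(m$sum_pixels)) {  # largest processed last, wins the cell
      prev <- obs[gr[i], gc[i], k, ]
      if (!is.na(prev["sum_pixels"])) {
        dropped <- rbind(dropped, data.frame(
          time_h = times[k], grid_row = gr[i], grid_col = gc[i],
          contour_id = prev["contour_id"], sum_pixels = prev["sum_pixels"]))
      }
      obs[gr[i], gc[i], k, ] <- c(m$contour_id[i], m$sum_pixels[i])
    }
  }
  tracks <- list()
  for (r in seq_len(n_rows)) {
    for (c in seq_len(n_cols)) {
      tracks[[length(tracks) + 1L]] <- structure(
        list(grid_cell = c(r, c),
             observations = data.frame(time_h = times,
                                       contour_id = obs[r, c, , "contour_id"],
                                       sum_pixels = obs[r, c, , "sum_pixels"])),
        class = "seed_track")
    }
  }
  attr(tracks, "dropped") <- dropped
  tracks
}

#' Growth curve of one seed track
#'
#' Calibrates each observation with the half-perimeter rule and computes
#' interval growth rates `(length[k+1] - length[k]) / (t[k+1] - t[k])` over
#' consecutive non-missing observations; a missing frame is skipped, the gap
#' spanning the longer interval.
#'
#' @param track a `seed_track` from [associate_seeds()] with at least 2
#'   non-missing observations.
#' @param cal a [calibration_ratio()].
#' @param amplify_offset,amplify_scale parameters of the amplified series
#'   (see [amplify_average()]).
#' @return object of class `growth_curve`: list with `times` (h),
#'   `lengths_cm`, `amplified`, `interval_rates` (cm/h, one per consecutive
#'   pair of retained times), `grid_cell`.
#' @export
growth_rates <- function(track, cal, amplify_offset = 1, amplify_scale = 2) {
  stopifnot(inherits(track, "seed_track"), inherits(cal, "calibration_ratio"))
  ob <- track$observations
  keep <- !is.na(ob$sum_pixels)
  if (sum(keep) < 2L) stop("need at least 2 non-missing observations")
  t <- ob$time_h[keep]
  len <- measure_radicle(ob$sum_pixels[keep], cal)
  rates <- diff(len) / diff(t)
  structure(list(times = t, lengths_cm = len,
                 amplified = amplify_average(len, amplify_offset, amplify_scale),
                 interval_rates = rates, grid_cell = track$grid_cell),
            class = "growth_curve")
}

#' Amplified-average visualization transform
#'
#' Magnifies growth trends for plotting: `out = (mean_lengths - offset) *
#' scale`. The conventional constants subtract 1 cm from the per-frame mean
#' radicle length and double the result; both are exposed as parameters since
#' the transform is a visualization aid, not a measurement.
#'
#' @param mean_lengths numeric vector (cm).
#' @param offset subtracted before scaling (default 1).
#' @param scale multiplier (default 2).
#' @export
amplify_average <- function(mean_lengths, offset = 1, scale = 2) {
  (mean_lengths - offset) * scale
}

#' Contour overlay coordinates in physical axis units
#'
#' Converts contour pixel coordinates to cm via the calibration ratio and
#' expresses them in axis units of `axis_unit_cm` (0.1 cm by default), with
#' frames arranged side by side in time order (frame k offset by
#' `(k-1) * frame_width` axis units on the x axis). Each contour gets a
#' label row with its cm length anchored beneath its bounding box.
#'
#' @param frame_contours list over frames of [contour_pixels()]-style
#'   data.frames (columns contour_id, row, col).
#' @param cal a [calibration_ratio()].
#' @param axis_unit_cm physical size of one axis unit (cm), > 0.
#' @param frame_width_px width of one frame in px (defaults to the
#'   calibration's image side).
#' @return list with `points` (frame, contour_id, x_axis_units,
#'   y_axis_units) and `labels` (frame, contour_id, length_cm,
#'   label_x_axis_units, label_y_axis_units).
#' @export
contour_overlay <- function(frame_contours, cal, axis_unit_cm = 0.1,
                            frame_width_px = cal$image_unilateral_pixel) {
  stopifnot(inherits(cal, "calibration_ratio"))
  if (axis_unit_cm <= 0) stop("axis_unit_cm must be positive")
  px_to_units <- cal$R / axis_unit_cm
  frame_offset <- frame_width_px * px_to_units
  points <- data.frame(frame = integer(), contour_id = integer(),
                       x_axis_units = numeric(), y_axis_units = numeric())
  labels <- data.frame(frame = integer(), contour_id = integer(),
                       length_cm = numeric(), label_x_axis_units = numeric(),
                       label_y_axis_units = numeric())
  for (k in seq_along(frame_contours)) {
    fc <- frame_contours[[k]]
    if (is.null(fc) || nrow(fc) == 0L) next
    points <- rbind(points, data.frame(
      frame = k, contour_id = fc$contour_id,
      x_axis_units = (fc$col - 1) * px_to_units + (k - 1) * frame_offset,
      y_axis_units = (fc$row - 1) * px_to_units))
    for (id in unique(fc$contour_id)) {
      sel <- fc$contour_id == id
      labels <- rbind(labels, data.frame(
        frame = k, contour_id = id,
        length_cm = measure_radicle(sum(sel), cal),
        label_x_axis_units = (min(fc$col[sel]) - 1) * px_to_units +
          (k - 1) * frame_offset,
        label_y_axis_units = (max(fc$row[sel]) + 4) * px_to_units))
    }
  }
  list(points = points, labels = labels)
}

#' Export seed tracks as CSV
#'
#' One row per (cell, frame): grid_row, grid_col, timestamp_h, sum_pixels,
#' length_cm (NA where the cell had no measurement).
#'
#' @param tracks list from [associate_seeds()].
#' @param cal a [calibration_ratio()].
#' @param path output CSV path.
#' @export
write_tracks_csv <- function(tracks, cal, path) {
  rows <- do.call(rbind, lapply(tracks, function(tr) {
    ob <- tr$observations
    data.frame(grid_row = tr$grid_cell[1], grid_col = tr$grid_cell[2],
               timestamp_h = ob$time_h, sum_pixels = ob$sum_pixels,
               length_cm = ifelse(is.na(ob$sum_pixels), NA,
                                  measure_radicle(ifelse(is.na(ob$sum_pixels), 0,
                                                         ob$sum_pixels), cal)))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
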