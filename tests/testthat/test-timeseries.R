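make_meas <- function(rows, cols, pix) {
  data.frame(contour_id = seq_along(rows), sum_pixels = pix,
             centroid_row = rows, centroid_col = cols,
             row_min = rows - 1, col_min = cols - 1,
             row_max = rows + 1, col_max = cols + 1)
}

test_that("measurements land in their tray cells; empty cells go missing", {
  # 2x2 layout on a 100x100 image: cells are 50x50
  frames <- list(list(time_h = 0, measurements = make_meas(
    c(20, 20, 80, 80), c(20, 80, 20, 80), c(100, 110, 120, 130))))
  tracks <- associate_seeds(frames, c(2, 2), c(100, 100))
  expect_length(tracks, 4)
  pix <- vapply(tracks, function(tr) tr$observations$sum_pixels[1], numeric(1))
  expect_equal(sort(pix), c(100, 110, 120, 130))

  # a frame with an empty cell records NA, not an error
  frames2 <- list(list(time_h = 0, measurements = make_meas(20, 20, 50)))
  tracks2 <- associate_seeds(frames2, c(2, 2), c(100, 100))
  n_obs <- sum(!is.na(vapply(tracks2, function(tr) tr$observations$sum_pixels[1],
                             numeric(1))))
  expect_equal(n_obs, 1)

  bad <- list(list(time_h = 0, measurements = make_meas(500, 20, 10)))
  expect_error(associate_seeds(bad, c(2, 2), c(100, 100)), "outside image")
})

test_that("the largest contour wins a contested cell and losers are logged", {
  set.seed(51)
  for (rep in 1:5) {
    pix <- sample(10:500, 3)
    m <- make_meas(c(20, 25, 30), c(20, 25, 30), pix)  # all in cell (1,1)
    tracks <- associate_seeds(list(list(time_h = 0, measurements = m)),
                              c(2, 2), c(100, 100))
    kept <- tracks[[1]]$observations$sum_pixels[1]
    expect_equal(kept, max(pix))  # brute-force max
    expect_equal(nrow(attr(tracks, "dropped")), 2)
  }
})

test_that("every measurement is assigned to exactly one track", {
  set.seed(57)
  m <- make_meas(stats::runif(12, 5, 95), stats::runif(12, 5, 95),
                 sample(1000, 12))
  tracks <- associate_seeds(list(list(time_h = 0, measurements = m)),
                            c(3, 3), c(100, 100))
  assigned <- unlist(lapply(tracks, function(tr) tr$observations$sum_pixels[1]))
  dropped <- attr(tracks, "dropped")$sum_pixels
  expect_setequal(c(assigned[!is.na(assigned)], dropped), m$sum_pixels)
})

test_that("growth rates recover constant, linear and phased schedules", {
  cal <- calibration_ratio(25, 1500)
  mk_track <- function(times, pix) {
    structure(list(grid_cell = c(1, 1),
                   observations = data.frame(time_h = times,
                                             contour_id = seq_along(times),
                                             sum_pixels = pix)),
              class = "seed_track")
  }
  const <- growth_rates(mk_track(0:4, rep(120, 5)), cal)
  expect_true(all(const$interval_rates == 0))

  # linear growth of 1 cm/h: 1 cm = 120 edge px at R = 1/60 (half-perimeter)
  lin <- growth_rates(mk_track(0:4, 120 * (1:5)), cal)
  expect_equal(lin$interval_rates, rep(1, 4))

  expect_error(growth_rates(mk_track(0, 120), cal), "at least 2")

  # missing frames span the longer interval
  gap <- mk_track(0:3, c(120, NA, NA, 480))
  g <- growth_rates(gap, cal)
  expect_equal(g$times, c(0, 3))
  expect_equal(g$interval_rates, (4 - 1) / 3)
})

test_that("phased synthetic series has its fastest interval in the fast phase", {
  cal <- calibration_ratio(25, 1500)
  sched <- phase_schedule()
  sp <- random_radicle_spec(c(1, 1), 1, 1, c(400, 400), length_px = 130,
                            rng_seed = 8)
  series <- generate_growth_series(sp, sched)
  frames <- lapply(series, function(fr) {
    e <- canny(fr$mask * 255)
    list(time_h = fr$time_h, measurements = label_contours(e))
  })
  tracks <- associate_seeds(frames, c(1, 1), c(400, 400))
  gc <- growth_rates(tracks[[1]], cal)
  best <- which.max(gc$interval_rates)
  expect_equal(sched$phase_labels[best], "fast")
})

test_that("amplify transform is the documented affine map", {
  expect_equal(amplify_average(2.5), 3.0)
  expect_equal(amplify_average(c(1, 2, 3), offset = 0, scale = 1), c(1, 2, 3))
  set.seed(61)
  x <- stats::runif(20, 0, 6)
  # order preservation
  expect_equal(order(amplify_average(x)), order(x))
  # composing two affine maps equals the composed map
  once <- amplify_average(amplify_average(x, 1, 2), 3, 4)
  expect_equal(once, (x * 2 * 4) + (-1 * 2 - 3) * 4)
})

test_that("contour overlay scales pixels into 0.1 cm axis units", {
  cal <- calibration_ratio(25, 1500)  # R = 1/60
  pt <- data.frame(contour_id = 1L, row = 1L, col = 1L)
  ov <- contour_overlay(list(pt), cal)
  expect_equal(ov$points$x_axis_units, 0)
  expect_equal(ov$points$y_axis_units, 0)

  seg <- data.frame(contour_id = 1L, row = rep(1L, 60), col = 1:60)
  ov <- contour_overlay(list(seg), cal)
  # 60 px * (1/60 cm/px) = 1 cm = 10 axis units of 0.1 cm
  expect_equal(diff(range(ov$points$x_axis_units)), 10, tolerance = 0.2)
  expect_equal(ov$labels$length_cm, measure_radicle(60, cal))

  expect_error(contour_overlay(list(seg), cal, axis_unit_cm = 0), "positive")

  # growing series: frame bounding-box width non-shrinking
  widths <- vapply(1:3, function(k) {
    s <- data.frame(contour_id = 1L, row = rep(1L, 20 * k), col = seq_len(20 * k))
    o <- contour_overlay(list(s), cal)
    diff(range(o$points$x_axis_units))
  }, numeric(1))
  expect_false(is.unsorted(widths))
})

test_that("track CSV export carries calibrated lengths and missing markers", {
  cal <- calibration_ratio(25, 1500)
  frames <- list(
    list(time_h = 1, measurements = make_meas(20, 20, 120)),
    list(time_h = 2, measurements = make_meas(c(20, 80), c(20, 80), c(240, 60))))
  tracks <- associate_seeds(frames, c(2, 2), c(100, 100))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks_csv(tracks, cal, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 4 * 2)
  got <- back[back$grid_row == 1 & back$grid_col == 1, ]
  expect_equal(got$length_cm, measure_radicle(c(120, 240), cal))
  expect_true(any(is.na(back$sum_pixels)))
})
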