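test_that("axis-aligned unit-thickness radicle rasterises to exactly its length", {
  sp <- radicle_spec(rbind(c(10.5, 10), c(10.5, 110)), thickness_px = 1,
                     image_size = c(50, 150))
  g <- generate_radicle_mask(sp)
  expect_equal(g$true_length_px, 100)
  expect_equal(sum(g$mask), 100)
  # vertical too
  spv <- radicle_spec(rbind(c(5, 20.5), c(45, 20.5)), thickness_px = 1,
                      image_size = c(60, 40))
  gv <- generate_radicle_mask(spv)
  expect_equal(gv$true_length_px, 40)
  expect_equal(sum(gv$mask), 40)
})

test_that("quarter-circle centerline reproduces the analytic arc length", {
  th <- seq(0, pi / 2, length.out = 37)
  ctrl <- cbind(70 - 60 * sin(th), 10 + 60 * cos(th))
  sp <- radicle_spec(ctrl, thickness_px = 1, image_size = c(100, 100))
  g <- generate_radicle_mask(sp)
  expect_equal(g$true_length_px, 30 * pi, tolerance = 1e-3)
})

test_that("spline arc length matches a dense 10000-segment polyline oracle", {
  set.seed(42)
  for (rep in 1:5) {
    ctrl <- cbind(stats::runif(6, 20, 180), stats::runif(6, 20, 180))
    sp <- radicle_spec(ctrl, image_size = c(200, 200))
    got <- generate_radicle_mask(sp)$true_length_px
    # independent dense evaluation of the same interpolating spline
    n_seg <- nrow(ctrl) - 1
    per <- ceiling(10000 / n_seg)
    ext <- rbind(ctrl[1, ], ctrl, ctrl[nrow(ctrl), ])
    pts <- NULL
    for (s in seq_len(n_seg)) {
      t <- seq(0, 1, length.out = per + 1)
      p0 <- ext[s, ]; p1 <- ext[s + 1, ]; p2 <- ext[s + 2, ]; p3 <- ext[s + 3, ]
      seg <- sapply(1:2, function(d) {
        0.5 * ((2 * p1[d]) + (-p0[d] + p2[d]) * t +
               (2 * p0[d] - 5 * p1[d] + 4 * p2[d] - p3[d]) * t^2 +
               (-p0[d] + 3 * p1[d] - 3 * p2[d] + p3[d]) * t^3)
      })
      pts <- rbind(pts, if (s == 1) seg else seg[-1, ])
    }
    oracle <- sum(sqrt(rowSums(diff(pts)^2)))
    expect_equal(got, oracle, tolerance = 1e-3)
  }
})

test_that("out-of-bounds centerlines fail naming the offending point", {
  sp <- radicle_spec(rbind(c(5, 5), c(5, 300)), image_size = c(50, 100))
  expect_error(generate_radicle_mask(sp), "exits image bounds")
})

test_that("tray generation honours layout, shapes and disjointness", {
  specs <- lapply(1:9, function(i) {
    random_radicle_spec(c((i - 1) %/% 3 + 1, (i - 1) %% 3 + 1), 3, 3,
                        c(450, 450), length_px = 60, rng_seed = i)
  })
  tray <- generate_tray(3, 3, specs, image_size = c(450, 450))
  expect_length(tray$mask_set$masks, 9)
  for (m in tray$mask_set$masks) expect_equal(dim(m), c(450L, 450L))
  # adjacent cells stay disjoint
  for (i in 1:8) for (j in (i + 1):9) {
    expect_equal(sum(tray$mask_set$masks[[i]] * tray$mask_set$masks[[j]]), 0)
  }
  expect_equal(nrow(tray$truth), 9)

  empty <- generate_tray(3, 3, list(), image_size = c(100, 100))
  expect_length(empty$mask_set$masks, 0)
  expect_true(all(empty$composite == 30))

  dup <- list(specs[[1]], specs[[1]])
  expect_error(generate_tray(3, 3, dup), "duplicate grid_cell")
})

test_that("growth series follows the schedule", {
  sp <- random_radicle_spec(c(1, 1), 1, 1, c(400, 400), length_px = 200,
                            rng_seed = 3)
  const <- growth_schedule(0:2, rep(80, 3))
  fr <- generate_growth_series(sp, const)
  expect_identical(fr[[1]]$mask, fr[[2]]$mask)
  expect_identical(fr[[2]]$mask, fr[[3]]$mask)

  lin <- growth_schedule(0:4, seq(50, 150, by = 25))
  fr <- generate_growth_series(sp, lin)
  lens <- vapply(fr, `[[`, numeric(1), "true_length_px")
  expect_equal(lens, seq(50, 150, by = 25), tolerance = 1 / 50)
  expect_false(is.unsorted(lens))

  phased <- phase_schedule()
  fr <- generate_growth_series(
    random_radicle_spec(c(1, 1), 1, 1, c(400, 400), length_px = 130, rng_seed = 5),
    phased)
  incr <- diff(vapply(fr, `[[`, numeric(1), "true_length_px"))
  by_phase <- tapply(incr, phased$phase_labels, mean)
  expect_gt(by_phase["fast"], by_phase["slow"])
  expect_gt(by_phase["slow"], by_phase["plateau"])

  over <- growth_schedule(0:1, c(100, 10000))
  expect_error(generate_growth_series(sp, over), "exceeds")
})

test_that("growth schedules validate their invariants", {
  expect_error(growth_schedule(c(0, 1), c(5, 4)), "non-decreasing")
  expect_error(growth_schedule(c(0, 1), c(5, 6, 7)), "equal length")
  expect_error(growth_schedule(c(0, 0), c(5, 6)), "strictly increasing")
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- generate_radicle_mask(random_radicle_spec(c(1, 1), 1, 1, c(300, 300),
                                                 length_px = 90, rng_seed = 11))
  b <- generate_radicle_mask(random_radicle_spec(c(1, 1), 1, 1, c(300, 300),
                                                 length_px = 90, rng_seed = 11))
  expect_identical(a$mask, b$mask)
  expect_identical(a$true_length_px, b$true_length_px)
  c <- generate_radicle_mask(random_radicle_spec(c(1, 1), 1, 1, c(300, 300),
                                                 length_px = 90, rng_seed = 12))
  expect_false(identical(a$mask, c$mask))
})

test_that("augmentation operators behave as exact pixel maps", {
  set.seed(7)
  img <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  expect_equal(augment_brightness(img, 1.0), img)
  expect_true(all(augment_brightness(img, 0.0) == 0))
  expect_true(all(augment_brightness(img, 3) <= 255))
  expect_error(augment_brightness(img, -0.5), "non-negative")

  expect_equal(augment_sharpen(matrix(100, 10, 10)), matrix(100, 10, 10))

  r <- img
  for (i in 1:4) r <- augment_rotate(r, 90)
  expect_identical(r, img)
  # rotation keeps binary masks binary
  m <- random_binary(15, 15) * 255
  expect_true(all(augment_rotate(m, 33) %in% c(0, 255)))
})
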