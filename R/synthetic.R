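#' Radicle specification for the synthetic generator
#'
#' Describes one synthetic radicle: a Catmull-Rom centerline through ordered
#' control points, rendered by sweeping a disc of diameter `thickness_px`
#' along the curve. Continuous coordinates put integer values at pixel
#' corners, so pixel `(i, j)` of the rendered matrix covers
#' `[i-1, i) x [j-1, j)`; an axis-aligned unit-thickness centerline of arc
#' length L placed on pixel-row centers rasterises to exactly L foreground
#' pixels.
#'
#' @param centerline_control_points numeric matrix (n x 2) of (row, col)
#'   control points in pixel units, n >= 2.
#' @param thickness_px positive integer radicle thickness; the swept disc has
#'   radius `floor(thickness_px / 2)`.
#' @param image_size integer vector `c(height, width)` in pixels.
#' @param grid_cell integer vector `c(row, col)` locating the seed in the
#'   tray layout (1-based).
#' @param rng_seed integer seed recorded with the spec; generators derived
#'   from a spec are bit-reproducible given this seed.
#' @return an object of class `radicle_spec`.
#' @export
radicle_spec <- function(centerline_control_points, thickness_px = 3L,
                         image_size = c(1500L, 1500L), grid_cell = c(1L, 1L),
                         rng_seed = 1L) {
  ctrl <- as.matrix(centerline_control_points)
  if (!is.numeric(ctrl) || ncol(ctrl) != 2L || nrow(ctrl) < 2L) {
    stop("centerline_control_points must be a numeric n x 2 matrix with n >= 2")
  }
  thickness_px <- as.integer(thickness_px)
  if (is.na(thickness_px) || thickness_px < 1L) stop("thickness_px must be >= 1")
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size < 1L)) {
    stop("image_size must be c(height, width) with positive entries")
  }
  structure(
    list(centerline_control_points = ctrl, thickness_px = thickness_px,
         image_size = image_size, grid_cell = as.integer(grid_cell),
         rng_seed = as.integer(rng_seed)),
    class = "radicle_spec"
  )
}

# Disc offsets (dr, dc) with dr^2 + dc^2 <= radius^2, radius = floor(t/2).
#' @keywords internal
#' @noRd
disc_offsets <- function(thickness_px) {
  r <- thickness_px %/% 2L
  if (r == 0L) return(matrix(c(0L, 0L), ncol = 2L))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  as.matrix(g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE])
}

# Rasterise a continuous polyline: resample at arc midpoints (step <= 0.1 px)
# so a half-open segment covers exactly its arc length in axis-aligned pixels,
# then floor into 1-based matrix indices.
#' @keywords internal
#' @noRd
rasterize_centerline <- function(pts, cumlen = NULL) {
  if (is.null(cumlen)) {
    d <- sqrt(rowSums(diff(pts)^2))
    cumlen <- c(0, cumsum(d))
  }
  total <- cumlen[length(cumlen)]
  if (total <= 0) {
    p <- pts[1, ]
    return(cbind(floor(p[1]) + 1L, floor(p[2]) + 1L))
  }
  m <- max(1L, ceiling(total / 0.1))
  s <- (seq_len(m) - 0.5) * total / m
  rr <- stats::approx(cumlen, pts[, 1], xout = s, ties = "ordered")$y
  cc <- stats::approx(cumlen, pts[, 2], xout = s, ties = "ordered")$y
  px <- unique(cbind(floor(rr) + 1L, floor(cc) + 1L))
  px
}

#' @keywords internal
#' @noRd
render_centerline_mask <- function(pts, thickness_px, image_size) {
  h <- image_size[1]; w <- image_size[2]
  rad <- thickness_px %/% 2L
  bad <- which(pts[, 1] < rad | pts[, 1] > h - rad |
               pts[, 2] < rad | pts[, 2] > w - rad)
  if (length(bad)) {
    stop(sprintf(
      "centerline point (%.2f, %.2f) exits image bounds %dx%d (thickness %d)",
      pts[bad[1], 1], pts[bad[1], 2], h, w, thickness_px))
  }
  px <- rasterize_centerline(pts)
  mask <- matrix(0L, h, w)
  off <- disc_offsets(thickness_px)
  for (k in seq_len(nrow(off))) {
    r <- px[, 1] + off[k, 1]
    c <- px[, 2] + off[k, 2]
    ok <- r >= 1L & r <= h & c >= 1L & c <= w
    mask[cbind(r[ok], c[ok])] <- 1L
  }
  mask
}

#' Render a synthetic radicle mask with exact centerline ground truth
#'
#' Sweeps a disc of diameter `thickness_px` along the spec's Catmull-Rom
#' centerline. The returned `true_length_px` is the arc length of the
#' centerline, computed by adaptive polyline refinement to 1e-3 px.
#'
#' @param spec a [radicle_spec()].
#' @return list with `mask` (integer 0/1 matrix of `image_size`) and
#'   `true_length_px`.
#' @export
generate_radicle_mask <- function(spec) {
  stopifnot(inherits(spec, "radicle_spec"))
  dense <- dense_centerline(spec$centerline_control_points)
  mask <- render_centerline_mask(dense$points, spec$thickness_px, spec$image_size)
  list(mask = mask,
       true_length_px = spline_arc_length(spec$centerline_control_points))
}

#' Draw a random curved radicle spec inside one tray cell
#'
#' Performs a bounded-curvature random walk from the cell centre (the seed
#' position), fits a centerline through it, and truncates it to approximately
#' `length_px`; ground truth is always the rendered centerline's own arc
#' length, not the requested target.
#'
#' @param grid_cell `c(row, col)` cell indices (1-based).
#' @param n_rows,n_cols tray layout dimensions.
#' @param image_size `c(height, width)` of the full image in px.
#' @param length_px requested centerline arc length in px.
#' @param thickness_px radicle thickness in px.
#' @param rng_seed integer seed; the walk is bit-reproducible given it.
#' @param max_turn_deg per-step heading change bound (degrees); controls
#'   curvature.
#' @return a [radicle_spec()].
#' @export
random_radicle_spec <- function(grid_cell, n_rows, n_cols,
                                image_size = c(1500L, 1500L),
                                length_px = 120, thickness_px = 3L,
                                rng_seed = 1L, max_turn_deg = 25) {
  h <- image_size[1]; w <- image_size[2]
  ch <- h / n_rows; cw <- w / n_cols
  r0 <- (grid_cell[1] - 1) * ch; c0 <- (grid_cell[2] - 1) * cw
  margin <- thickness_px + 2
  lo <- c(r0 + margin, c0 + margin)
  hi <- c(r0 + ch - margin, c0 + cw - margin)
  if (any(hi - lo < 4)) stop("cell too small for the requested thickness")

  pts <- withr::with_seed(rng_seed, {
    gen_len <- 1.25 * length_px + 10
    step <- max(6, min(length_px / 10, min(hi - lo) / 4))
    ang <- stats::runif(1, 0, 2 * pi)
    turn <- max_turn_deg * pi / 180
    pos <- (lo + hi) / 2
    walk <- matrix(pos, ncol = 2)
    travelled <- 0
    while (travelled < gen_len) {
      ang <- ang + stats::runif(1, -turn, turn)
      cand <- pos + step * c(sin(ang), cos(ang))
      for (ax in 1:2) {
        if (cand[ax] < lo[ax] || cand[ax] > hi[ax]) {
          # reflect the offending velocity component back into the cell
          v <- cand - pos
          v[ax] <- -v[ax]
          cand <- pos + v
          ang <- atan2(cand[1] - pos[1], cand[2] - pos[2])
        }
      }
      cand <- pmin(pmax(cand, lo), hi)
      travelled <- travelled + sqrt(sum((cand - pos)^2))
      pos <- cand
      walk <- rbind(walk, pos)
    }
    walk
  })

  dense <- dense_centerline(pts)
  cut <- truncate_centerline(dense, min(length_px, max(dense$cumlen)))
  # resample sparse control points along the truncated curve
  n_ctrl <- max(4L, min(nrow(cut), as.integer(round(length_px / 12))))
  idx <- unique(round(seq(1, nrow(cut), length.out = n_ctrl)))
  radicle_spec(cut[idx, , drop = FALSE], thickness_px = thickness_px,
               image_size = image_size, grid_cell = grid_cell,
               rng_seed = rng_seed)
}

#' Generate a tray of seeds with per-instance radicle masks
#'
#' Emulates one tray image: seeds arranged on an `n_rows x n_cols` grid
#' (6 x 6 by default use), each with a radicle rendered from its spec. The
#' composite is an 8-bit grayscale image with elliptical seed bodies at each
#' radicle origin plus the radicles themselves.
#'
#' @param n_rows,n_cols tray layout.
#' @param specs list of [radicle_spec()]s with unique `grid_cell`s.
#' @param image_size `c(height, width)`; default 1500 x 1500.
#' @return list with `mask_set` (an [instance_mask_set()], one mask per
#'   spec), `composite` (integer matrix, values 0..255), and `truth`
#'   (data.frame: grid_row, grid_col, true_length_px).
#' @export
generate_tray <- function(n_rows, n_cols, specs, image_size = c(1500L, 1500L)) {
  cells <- vapply(specs, function(s) paste(s$grid_cell, collapse = ","), "")
  if (anyDuplicated(cells)) {
    stop("duplicate grid_cell: ", cells[duplicated(cells)][1])
  }
  for (s in specs) {
    if (any(s$grid_cell < 1L) || s$grid_cell[1] > n_rows || s$grid_cell[2] > n_cols) {
      stop("grid_cell out of layout bounds: ", paste(s$grid_cell, collapse = ","))
    }
  }
  h <- image_size[1]; w <- image_size[2]
  composite <- matrix(30L, h, w)
  masks <- vector("list", length(specs))
  truth <- data.frame(grid_row = integer(), grid_col = integer(),
                      true_length_px = numeric())
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    g <- generate_radicle_mask(s)
    masks[[i]] <- g$mask
    composite[g$mask == 1L] <- 230L
    # seed body: axis-aligned ellipse at the centerline origin
    p0 <- s$centerline_control_points[1, ]
    a <- 14; b <- 10
    rr <- max(1L, floor(p0[1] - a)):min(h, ceiling(p0[1] + a))
    cc <- max(1L, floor(p0[2] - b)):min(w, ceiling(p0[2] + b))
    cy <- outer((rr - 0.5 - p0[1])^2 / a^2, (cc - 0.5 - p0[2])^2 / b^2, "+") <= 1
    composite[rr, cc][cy] <- 200L
    truth <- rbind(truth, data.frame(grid_row = s$grid_cell[1],
                                     grid_col = s$grid_cell[2],
                                     true_length_px = g$true_length_px))
  }
  list(mask_set = instance_mask_set(masks, original_size = image_size),
       composite = composite, truth = truth)
}

#' Growth schedule for a radicle time series
#'
#' @param frame_times ordered timestamps in hours.
#' @param target_lengths_px non-decreasing target centerline lengths (px),
#'   one per frame.
#' @param phase_labels optional character vector, one per interval between
#'   consecutive frames, from `c("slow", "plateau", "fast")`.
#' @return object of class `growth_schedule`.
#' @export
growth_schedule <- function(frame_times, target_lengths_px, phase_labels = NULL) {
  if (length(frame_times) != length(target_lengths_px)) {
    stop("frame_times and target_lengths_px must have equal length")
  }
  if (is.unsorted(frame_times, strictly = TRUE)) {
    stop("frame_times must be strictly increasing")
  }
  if (any(target_lengths_px < 0) || is.unsorted(target_lengths_px)) {
    stop("target_lengths_px must be non-negative and non-decreasing")
  }
  if (!is.null(phase_labels)) {
    if (length(phase_labels) != length(frame_times) - 1L) {
      stop("need one phase label per interval")
    }
    stopifnot(all(phase_labels %in% c("slow", "plateau", "fast")))
  }
  structure(list(frame_times = as.numeric(frame_times),
                 target_lengths_px = as.numeric(target_lengths_px),
                 phase_labels = phase_labels),
            class = "growth_schedule")
}

#' Standard slow / plateau / fast germination schedule
#'
#' Emulates the germination pattern seen in hourly time-lapse imagery: an
#' initial slow elongation, a plateau with little change, then a phase where
#' the growth rate reaches its maximum. Hourly frames by default.
#'
#' @param n_slow,n_plateau,n_fast number of intervals per phase.
#' @param rate_slow,rate_plateau,rate_fast elongation per interval in px.
#' @param start_px initial length (px).
#' @param dt_hours frame spacing (hours).
#' @export
phase_schedule <- function(n_slow = 2L, n_plateau = 3L, n_fast = 2L,
                           rate_slow = 8, rate_plateau = 1, rate_fast = 30,
                           start_px = 40, dt_hours = 1) {
  rates <- c(rep(rate_slow, n_slow), rep(rate_plateau, n_plateau),
             rep(rate_fast, n_fast))
  labels <- c(rep("slow", n_slow), rep("plateau", n_plateau),
              rep("fast", n_fast))
  lens <- start_px + c(0, cumsum(rates))
  growth_schedule(seq_along(lens) * dt_hours - dt_hours, lens, labels)
}

#' Generate a growth series of masks from one spec and a schedule
#'
#' Frame k's centerline is the spec's centerline truncated to
#' `target_lengths_px[k]`; the reported true length reproduces the schedule
#' to within 1 px (rasterisation-independent: it is the truncated curve's
#' arc length).
#'
#' @param spec a [radicle_spec()] whose full centerline is at least as long
#'   as the schedule's maximum target.
#' @param schedule a [growth_schedule()].
#' @return list of frames, each `list(time_h, mask, true_length_px)`.
#' @export
generate_growth_series <- function(spec, schedule) {
  stopifnot(inherits(spec, "radicle_spec"), inherits(schedule, "growth_schedule"))
  dense <- dense_centerline(spec$centerline_control_points)
  lapply(seq_along(schedule$frame_times), function(k) {
    pts <- truncate_centerline(dense, schedule$target_lengths_px[k])
    mask <- render_centerline_mask(pts, spec$thickness_px, spec$image_size)
    list(time_h = schedule$frame_times[k], mask = mask,
         true_length_px = polyline_length(pts))
  })
}
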