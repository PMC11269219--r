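# Internal centerline geometry: Catmull-Rom splines through control points,
# arc-length computation by adaptive polyline refinement, and arc-length
# truncation. Continuous coordinates are (row, col) with integer values at
# pixel corners; pixel (i, j) of an R matrix covers [i-1, i) x [j-1, j).

#' @keywords internal
#' @noRd
catmull_rom_segment <- function(p0, p1, p2, p3, t) {
  # uniform Catmull-Rom basis; t is a vector in [0, 1]
  t2 <- t * t
  t3 <- t2 * t
  b0 <- -0.5 * t3 + t2 - 0.5 * t
  b1 <- 1.5 * t3 - 2.5 * t2 + 1
  b2 <- -1.5 * t3 + 2 * t2 + 0.5 * t
  b3 <- 0.5 * t3 - 0.5 * t2
  cbind(
    b0 * p0[1] + b1 * p1[1] + b2 * p2[1] + b3 * p3[1],
    b0 * p0[2] + b1 * p1[2] + b2 * p2[2] + b3 * p3[2]
  )
}

# Sample the Catmull-Rom spline through `ctrl` (n x 2 matrix, n >= 2) with
# `n_per_seg` points per segment. End segments use duplicated end points so
# the curve interpolates every control point. Returns an m x 2 matrix whose
# first and last rows are the first and last control points.
#' @keywords internal
#' @noRd
catmull_rom_polyline <- function(ctrl, n_per_seg = 32L) {
  ctrl <- as.matrix(ctrl)
  n <- nrow(ctrl)
  if (n < 2L) stop("centerline needs at least 2 control points")
  if (n == 2L) {
    t <- seq(0, 1, length.out = max(2L, n_per_seg + 1L))
    return(cbind(
      ctrl[1, 1] + t * (ctrl[2, 1] - ctrl[1, 1]),
      ctrl[1, 2] + t * (ctrl[2, 2] - ctrl[1, 2])
    ))
  }
  ext <- rbind(ctrl[1, ], ctrl, ctrl[n, ])
  t <- seq(0, 1, length.out = n_per_seg + 1L)
  pieces <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    pts <- catmull_rom_segment(ext[s, ], ext[s + 1, ], ext[s + 2, ], ext[s + 3, ], t)
    pieces[[s]] <- if (s == 1L) pts else pts[-1, , drop = FALSE]
  }
  do.call(rbind, pieces)
}

#' @keywords internal
#' @noRd
polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  d <- diff(pts)
  sum(sqrt(d[, 1]^2 + d[, 2]^2))
}

# Arc length of the spline through `ctrl`, refining the polyline until two
# successive doublings of the per-segment sample count agree to `tol` px.
#' @keywords internal
#' @noRd
spline_arc_length <- function(ctrl, tol = 1e-3, n0 = 16L, max_n = 4096L) {
  n <- n0
  len <- polyline_length(catmull_rom_polyline(ctrl, n))
  repeat {
    n <- n * 2L
    len2 <- polyline_length(catmull_rom_polyline(ctrl, n))
    if (abs(len2 - len) <= tol || n >= max_n) return(len2)
    len <- len2
  }
}

# Dense centerline sampled finely enough for rasterisation (step <= `step` px
# along every chord), with cumulative arc length attached.
#' @keywords internal
#' @noRd
dense_centerline <- function(ctrl, step = 0.1, n_per_seg = 256L) {
  pts <- catmull_rom_polyline(ctrl, n_per_seg)
  d <- sqrt(rowSums(diff(pts)^2))
  while (max(d) > step && n_per_seg < 16384L) {
    n_per_seg <- n_per_seg * 2L
    pts <- catmull_rom_polyline(ctrl, n_per_seg)
    d <- sqrt(rowSums(diff(pts)^2))
  }
  list(points = pts, cumlen = c(0, cumsum(d)))
}

# Truncate a dense centerline at arc length `target`; the final point is
# interpolated exactly on the curve chord.
#' @keywords internal
#' @noRd
truncate_centerline <- function(dense, target) {
  cl <- dense$cumlen
  total <- cl[length(cl)]
  if (target > total + 1e-9) {
    stop(sprintf("target length %.3f px exceeds renderable centerline (%.3f px)",
                 target, total))
  }
  if (target >= total) return(dense$points)
  k <- findInterval(target, cl, rightmost.closed = TRUE)
  k <- max(1L, k)
  pts <- dense$points[seq_len(k), , drop = FALSE]
  if (cl[k] < target) {
    frac <- (target - cl[k]) / (cl[k + 1L] - cl[k])
    p <- dense$points[k, ] + frac * (dense$points[k + 1L, ] - dense$points[k, ])
    pts <- rbind(pts, p)
  }
  pts
}
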