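# From-scratch Canny chain: Gaussian smoothing -> Sobel gradients ->
# non-maximum suppression -> double-threshold hysteresis. Operates on 8-bit
# images held as numeric matrices; all thresholds are on the 8-bit gradient
# scale.

# Symmetric (edge-including) reflection of out-of-range indices, valid for
# arbitrary padding widths.
#' @keywords internal
#' @noRd
reflect_index <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  j[j < 0L] <- j[j < 0L] + 2L * n
  ifelse(j >= n, 2L * n - 1L - j, j) + 1L
}

# 2-D cross-correlation with a (kh x kw) kernel, reflected borders, output
# the size of the input. Vectorised as a sum of shifted copies.
#' @keywords internal
#' @noRd
conv2_reflect <- function(m, k) {
  kh <- nrow(k); kw <- ncol(k)
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  pad <- m[reflect_index((1L - ph):(h + ph), h),
           reflect_index((1L - pw):(w + pw), w), drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      if (k[i, j] == 0) next
      out <- out + k[i, j] * pad[i:(i + h - 1L), j:(j + w - 1L), drop = FALSE]
    }
  }
  out
}

#' Canny parameter set
#'
#' @param sigma Gaussian standard deviation (px); must be positive.
#' @param kernel_size odd Gaussian kernel side length.
#' @param low_threshold,high_threshold hysteresis thresholds on the 8-bit
#'   gradient-magnitude scale, `0 <= low < high`.
#' @export
canny_params <- function(sigma = 1.4, kernel_size = 5L,
                         low_threshold = 50, high_threshold = 150) {
  if (sigma <= 0) stop("sigma must be positive")
  kernel_size <- as.integer(kernel_size)
  if (kernel_size < 1L || kernel_size %% 2L == 0L) stop("kernel_size must be odd and positive")
  if (low_threshold < 0 || low_threshold >= high_threshold) {
    stop("thresholds must satisfy 0 <= low < high")
  }
  structure(list(sigma = sigma, kernel_size = kernel_size,
                 low_threshold = low_threshold, high_threshold = high_threshold),
            class = "canny_params")
}

#' @keywords internal
#' @noRd
gaussian_kernel <- function(sigma, kernel_size) {
  r <- (kernel_size - 1L) %/% 2L
  x <- -r:r
  k <- exp(-outer(x^2, x^2, "+") / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian smoothing
#'
#' Convolves with a normalised sampled Gaussian (weights sum to 1); borders
#' are handled by symmetric reflection, so a constant image is a fixed point.
#'
#' @param image numeric matrix.
#' @param sigma positive standard deviation (px).
#' @param kernel_size odd kernel side length.
#' @export
gaussian_smooth <- function(image, sigma = 1.4, kernel_size = 5L) {
  if (kernel_size %% 2L == 0L) stop("kernel_size must be odd")
  if (sigma <= 0) stop("sigma must be positive")
  if (kernel_size == 1L) return(image + 0)
  conv2_reflect(image, gaussian_kernel(sigma, kernel_size))
}

#' Sobel gradient field
#'
#' 3x3 Sobel kernels with reflected borders. `magnitude` is the Euclidean
#' norm `sqrt(Gx^2 + Gy^2)`; `direction` is `atan2(Gy, Gx)` with the row
#' axis (y) pointing down.
#'
#' @param image numeric matrix, at least 3x3.
#' @return list of class `gradient_field` with `magnitude`, `direction`,
#'   `gx`, `gy`.
#' @export
sobel_gradients <- function(image) {
  if (nrow(image) < 3L || ncol(image) < 3L) stop("image must be at least 3x3")
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)        # d/dcol
  ky <- t(kx)                                                 # d/drow
  gx <- conv2_reflect(image, kx)
  gy <- conv2_reflect(image, ky)
  structure(list(magnitude = sqrt(gx^2 + gy^2),
                 direction = atan2(gy, gx), gx = gx, gy = gy),
            class = "gradient_field")
}

#' Non-maximum suppression
#'
#' Thins the gradient magnitude: a pixel survives iff its magnitude is `>=`
#' both neighbours along its gradient direction, quantised to 4 bins
#' (0, 45, 90, 135 degrees). Out-of-image neighbours count as 0. Ties are
#' kept so plateau edges survive.
#'
#' @param field a `gradient_field` from [sobel_gradients()].
#' @return thinned magnitude matrix (suppressed pixels set to 0).
#' @export
non_max_suppress <- function(field) {
  stopifnot(inherits(field, "gradient_field"))
  mag <- field$magnitude
  h <- nrow(mag); w <- ncol(mag)
  deg <- (field$direction * 180 / pi) %% 180
  # bin -> neighbour offset (drow, dcol): 0 deg gradient points along cols
  bin <- integer(length(deg))
  bin[deg < 22.5 | deg >= 157.5] <- 1L   # (0, 1)
  bin[deg >= 22.5 & deg < 67.5] <- 2L    # (1, 1)
  bin[deg >= 67.5 & deg < 112.5] <- 3L   # (1, 0)
  bin[deg >= 112.5 & deg < 157.5] <- 4L  # (1, -1)
  offs <- rbind(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))

  pad <- matrix(0, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mag
  nb <- function(dr, dc) pad[(2L + dr):(h + 1L + dr), (2L + dc):(w + 1L + dc)]
  keep <- matrix(FALSE, h, w)
  for (b in 1:4) {
    sel <- matrix(bin == b, h, w)
    if (!any(sel)) next
    fwd <- nb(offs[b, 1], offs[b, 2])
    bwd <- nb(-offs[b, 1], -offs[b, 2])
    keep[sel] <- mag[sel] >= fwd[sel] & mag[sel] >= bwd[sel]
  }
  out <- mag
  out[!keep] <- 0
  out
}

#' Double-threshold hysteresis
#'
#' Pixels with magnitude `>= high` are strong edges; pixels in `[low, high)`
#' are weak and kept only if 8-connected (transitively) to a strong pixel.
#'
#' @param thinned magnitude matrix (typically from [non_max_suppress()]).
#' @param low,high thresholds with `0 <= low < high`.
#' @return binary edge map (integer 0/1 matrix) of class `edge_map`.
#' @export
hysteresis_threshold <- function(thinned, low, high) {
  if (low < 0 || low >= high) stop("thresholds must satisfy 0 <= low < high")
  strong <- thinned >= high
  cand <- thinned >= low
  if (!any(strong)) {
    return(structure(matrix(0L, nrow(thinned), ncol(thinned)), class = "edge_map"))
  }
  lab <- label_components8(cand)
  keep_labels <- unique(lab$labels[strong[cand]])
  out <- matrix(0L, nrow(thinned), ncol(thinned))
  out[cand][lab$labels %in% keep_labels] <- 1L
  structure(out, class = "edge_map")
}

#' Full Canny edge detection
#'
#' Composition smooth -> Sobel gradients -> non-maximum suppression ->
#' hysteresis; deterministic given the image and parameters.
#'
#' @param image 8-bit numeric matrix.
#' @param params a [canny_params()].
#' @return binary `edge_map` matrix (0/1) the size of the input.
#' @export
canny <- function(image, params = canny_params()) {
  stopifnot(inherits(params, "canny_params"))
  sm <- gaussian_smooth(image, params$sigma, params$kernel_size)
  gf <- sobel_gradients(sm)
  th <- non_max_suppress(gf)
  hysteresis_threshold(th, params$low_threshold, params$high_threshold)
}
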