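# Data-augmentation operators used when building germination image datasets:
# brightness scaling, unsharp-style sharpening, and rotation. All operate on
# 8-bit images held as numeric/integer matrices with values in [0, 255].

#' @keywords internal
#' @noRd
check_8bit <- function(image) {
  if (!is.matrix(image) || !is.numeric(image)) stop("image must be a numeric matrix")
  if (any(image < 0 | image > 255)) stop("image values must lie in [0, 255]")
  image
}

#' Brightness augmentation
#'
#' Multiplies intensities by `factor` and clamps to `[0, 255]`; `factor < 1`
#' darkens, `factor > 1` brightens.
#'
#' @param image 8-bit image matrix.
#' @param factor non-negative multiplier.
#' @export
augment_brightness <- function(image, factor) {
  check_8bit(image)
  if (!is.numeric(factor) || length(factor) != 1L || factor < 0) {
    stop("factor must be a single non-negative number")
  }
  pmin(pmax(image * factor, 0), 255)
}

#' Sharpen augmentation
#'
#' Applies the 3x3 Laplacian-based sharpening kernel
#' `[0,-1,0; -1,5,-1; 0,-1,0]` with reflected borders, then clamps to
#' `[0, 255]`.
#'
#' @param image 8-bit image matrix.
#' @export
augment_sharpen <- function(image) {
  check_8bit(image)
  k <- matrix(c(0, -1, 0, -1, 5, -1, 0, -1, 0), 3, 3)
  pmin(pmax(conv2_reflect(image, k), 0), 255)
}

#' Rotation augmentation
#'
#' Rotates about the image centre. Multiples of 90 degrees are exact pixel
#' permutations (counter-clockwise); other angles use nearest-neighbour
#' resampling so binary masks stay binary, with out-of-frame pixels set to 0.
#'
#' @param image 8-bit image matrix.
#' @param angle_deg rotation angle in degrees, counter-clockwise.
#' @export
augment_rotate <- function(image, angle_deg) {
  check_8bit(image)
  a <- angle_deg %% 360
  if (a %% 90 == 0) {
    k <- (a %/% 90) %% 4
    out <- image
    for (i in seq_len(k)) {
      # one exact 90-degree CCW turn: reverse columns then transpose
      out <- t(out[, rev(seq_len(ncol(out))), drop = FALSE])
    }
    return(out)
  }
  h <- nrow(image); w <- ncol(image)
  th <- a * pi / 180
  cy <- h / 2; cx <- w / 2
  # inverse-map output pixel centres into the source image
  oc <- expand.grid(r = seq_len(h), c = seq_len(w))
  yr <- oc$r - 0.5 - cy; xc <- oc$c - 0.5 - cx
  sy <- cy + (cos(th) * yr + sin(th) * xc)
  sx <- cx + (-sin(th) * yr + cos(th) * xc)
  sr <- floor(sy) + 1L; sc <- floor(sx) + 1L
  ok <- sr >= 1L & sr <= h & sc >= 1L & sc <= w
  out <- matrix(0, h, w)
  out[cbind(oc$r[ok], oc$c[ok])] <- image[cbind(sr[ok], sc[ok])]
  out
}
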