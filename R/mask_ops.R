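#' Per-instance binary mask collection
#'
#' Holds one binary (0/1) mask per detected seed radicle, possibly at
#' different resolutions than the original image, awaiting merge.
#'
#' @param masks list of integer/numeric matrices with values in `{0, 1}`;
#'   may be empty.
#' @param original_size `c(height, width)` of the original image in px.
#' @return object of class `instance_mask_set`.
#' @export
instance_mask_set <- function(masks, original_size) {
  stopifnot(is.list(masks))
  original_size <- as.integer(original_size)
  if (length(original_size) != 2L || any(original_size < 1L)) {
    stop("original_size must be positive c(height, width)")
  }
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    if (!is.matrix(m) || !is.numeric(m)) stop("mask ", i, " is not a numeric matrix")
    if (!all(m %in% c(0, 1))) stop("mask ", i, " has values outside {0, 1}")
  }
  structure(list(masks = masks, original_size = original_size),
            class = "instance_mask_set")
}

# Nearest-neighbour resize so binary masks stay binary.
#' @keywords internal
#' @noRd
resize_nearest <- function(m, size) {
  h <- nrow(m); w <- ncol(m)
  if (h == size[1] && w == size[2]) return(m)
  ri <- pmin(h, floor((seq_len(size[1]) - 0.5) * h / size[1]) + 1L)
  ci <- pmin(w, floor((seq_len(size[2]) - 0.5) * w / size[2]) + 1L)
  m[ri, ci, drop = FALSE]
}

#' Merge per-instance masks into one binary image
#'
#' Reimplements the merged-mask post-processing of segmentation output: each
#' instance mask is cast to 8-bit, resized (nearest neighbour) to the
#' original image size, the masks are summed, and the sum is thresholded so
#' the output contains exactly the values `{0, 255}` — the union of all
#' instance foregrounds. An empty set yields an all-zero mask.
#'
#' @param set an [instance_mask_set()].
#' @return object of class `merged_mask`: list with `grid` (integer matrix,
#'   values 0/255) and `size`.
#' @export
merge_masks <- function(set) {
  stopifnot(inherits(set, "instance_mask_set"))
  size <- set$original_size
  acc <- matrix(0L, size[1], size[2])
  for (m in set$masks) {
    acc <- acc + resize_nearest(storage_uint8(m), size)
  }
  grid <- matrix(0L, size[1], size[2])
  grid[acc > 0L] <- 255L
  structure(list(grid = grid, size = size), class = "merged_mask")
}

#' @keywords internal
#' @noRd
storage_uint8 <- function(m) {
  if (!all(m %in% c(0, 1))) stop("mask has values outside {0, 1}")
  storage.mode(m) <- "integer"
  m
}

#' Write / read a merged mask as lossless 8-bit grayscale PNG
#'
#' `write_mask_png` defaults to the conventional output filename `"in.png"`
#' in `dir`. `read_mask_png` refuses images whose pixels are not exactly 0
#' or 255, naming the first offending pixel.
#'
#' @param mask a `merged_mask` (or a 0/255 integer matrix).
#' @param path output file path; default `file.path(dir, "in.png")`.
#' @param dir directory used when `path` is missing.
#' @return `write_mask_png` returns `path` invisibly; `read_mask_png`
#'   returns a `merged_mask`.
#' @export
write_mask_png <- function(mask, path = file.path(dir, "in.png"), dir = ".") {
  grid <- if (inherits(mask, "merged_mask")) mask$grid else mask
  if (!all(grid %in% c(0L, 255L))) stop("mask values must be exactly {0, 255}")
  png::writePNG(grid / 255, target = path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  grid <- round(arr * 255)
  bad <- which(!(grid %in% c(0, 255)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(grid))
    stop(sprintf("pixel (%d, %d) has value %g, expected 0 or 255",
                 rc[1], rc[2], grid[bad[1]]))
  }
  storage.mode(grid) <- "integer"
  structure(list(grid = grid, size = dim(grid)), class = "merged_mask")
}
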