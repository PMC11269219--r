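#' Physical calibration ratio (cm per pixel)
#'
#' `R = actual_length_cm / image_unilateral_pixel`: the physical side length
#' of the imaged field divided by the image side length in pixels. With the
#' standard tray setup (25 cm field, 1500 px image side) `R = 1/60` cm/px.
#' The quotient is carried unrounded.
#'
#' @param actual_length_cm physical side of the imaged field (cm), > 0.
#' @param image_unilateral_pixel image side length (px), > 0.
#' @return object of class `calibration_ratio` with field `R` (cm/px).
#' @export
calibration_ratio <- function(actual_length_cm = 25, image_unilateral_pixel = 1500L) {
  if (!is.numeric(actual_length_cm) || actual_length_cm <= 0) {
    stop("actual_length_cm must be positive")
  }
  if (!is.numeric(image_unilateral_pixel) || image_unilateral_pixel <= 0) {
    stop("image_unilateral_pixel must be positive")
  }
  structure(list(actual_length_cm = actual_length_cm,
                 image_unilateral_pixel = as.integer(image_unilateral_pixel),
                 R = actual_length_cm / image_unilateral_pixel),
            class = "calibration_ratio")
}

#' Count edge pixels in a binary edge map
#'
#' Every nonzero pixel contributes exactly 1, regardless of diagonal
#' adjacency (no sqrt(2) weighting), matching pixel-count-based contour
#' length.
#'
#' @param edge binary edge map (0/1 matrix, e.g. from [canny()]).
#' @export
count_edge_pixels <- function(edge) {
  grid <- unclass(edge)
  if (!all(grid %in% c(0, 1))) stop("edge map must be binary (0/1)")
  sum(grid != 0)
}

#' Label edge contours as 8-connected components
#'
#' Partitions the edge pixels into 8-connected components and summarises
#' each with its pixel count, centroid and bounding box. Components are
#' ordered by `(row_min, col_min)` and given ids `1..n` in that order.
#' Coordinates are 1-based matrix indices.
#'
#' @param edge binary edge map.
#' @return data.frame with columns `contour_id`, `sum_pixels`,
#'   `centroid_row`, `centroid_col`, `row_min`, `col_min`, `row_max`,
#'   `col_max`.
#' @export
label_contours <- function(edge) {
  grid <- unclass(edge)
  if (!all(grid %in% c(0, 1))) stop("edge map must be binary (0/1)")
  lab <- label_components8(grid)
  empty <- data.frame(contour_id = integer(), sum_pixels = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      row_min = integer(), col_min = integer(),
                      row_max = integer(), col_max = integer())
  if (lab$n_components == 0L) return(empty)
  out <- do.call(rbind, lapply(seq_len(lab$n_components), function(l) {
    sel <- lab$labels == l
    r <- lab$rows[sel]; c <- lab$cols[sel]
    data.frame(contour_id = NA_integer_, sum_pixels = sum(sel),
               centroid_row = mean(r), centroid_col = mean(c),
               row_min = min(r), col_min = min(c),
               row_max = max(r), col_max = max(c))
  }))
  out <- out[order(out$row_min, out$col_min), , drop = FALSE]
  out$contour_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Per-pixel contour membership
#'
#' Companion to [label_contours()]: returns the pixel coordinates of every
#' contour, with `contour_id`s matching [label_contours()]'s ordering.
#'
#' @param edge binary edge map.
#' @return data.frame with columns `contour_id`, `row`, `col` (1-based).
#' @export
contour_pixels <- function(edge) {
  grid <- unclass(edge)
  if (!all(grid %in% c(0, 1))) stop("edge map must be binary (0/1)")
  lab <- label_components8(grid)
  if (lab$n_components == 0L) {
    return(data.frame(contour_id = integer(), row = integer(), col = integer()))
  }
  # reproduce label_contours' (row_min, col_min) ordering
  rmin <- tapply(lab$rows, lab$labels, min)
  cmin <- tapply(lab$cols, lab$labels, min)
  ord <- order(rmin, cmin)
  remap <- integer(lab$n_components)
  remap[ord] <- seq_len(lab$n_components)
  out <- data.frame(contour_id = remap[lab$labels], row = lab$rows,
                    col = lab$cols)
  out[order(out$contour_id, out$col, out$row), , drop = FALSE]
}

#' Half-perimeter radicle length in cm
#'
#' Converts an edge-pixel count into a physical length: the closed edge
#' contour of a thin elongated shape has roughly twice the shape's length in
#' boundary pixels, so `length_cm = sum_pixels / 2 * R`. Linear in both
#' arguments; no correction is applied for radicle thickness (the resulting
#' positive bias is about `thickness/2 * R`).
#'
#' @param sum_pixels non-negative edge-pixel count(s).
#' @param cal a [calibration_ratio()].
#' @return radicle length(s) in cm.
#' @export
measure_radicle <- function(sum_pixels, cal) {
  stopifnot(inherits(cal, "calibration_ratio"))
  if (any(sum_pixels < 0)) stop("sum_pixels must be non-negative")
  sum_pixels / 2 * cal$R
}

#' Measure every contour of an edge map
#'
#' Convenience composition of [label_contours()] and [measure_radicle()].
#'
#' @inheritParams label_contours
#' @param cal a [calibration_ratio()].
#' @return the [label_contours()] data.frame with a `length_cm` column.
#' @export
measure_contours <- function(edge, cal) {
  m <- label_contours(edge)
  m$length_cm <- measure_radicle(m$sum_pixels, cal)
  m
}

# --- annotation -------------------------------------------------------------

# 3x5 bitmap glyphs for measurement labels.
#' @keywords internal
#' @noRd
label_font <- function() {
  g <- list(
    "0" = c("111", "101", "101", "101", "111"),
    "1" = c("010", "110", "010", "010", "111"),
    "2" = c("111", "001", "111", "100", "111"),
    "3" = c("111", "001", "111", "001", "111"),
    "4" = c("101", "101", "111", "001", "001"),
    "5" = c("111", "100", "111", "001", "111"),
    "6" = c("111", "100", "111", "101", "111"),
    "7" = c("111", "001", "010", "010", "010"),
    "8" = c("111", "101", "111", "101", "111"),
    "9" = c("111", "101", "111", "001", "111"),
    "." = c("000", "000", "000", "000", "010"),
    "p" = c("000", "110", "101", "110", "100"),
    "x" = c("000", "101", "010", "101", "000"),
    "c" = c("000", "011", "100", "100", "011"),
    "m" = c("000", "110", "111", "101", "101"),
    " " = c("000", "000", "000", "000", "000")
  )
  lapply(g, function(rows) {
    do.call(rbind, lapply(rows, function(s) as.integer(strsplit(s, "")[[1]])))
  })
}

#' @keywords internal
#' @noRd
stamp_text <- function(image, row, col, text, value = 255) {
  font <- label_font()
  h <- nrow(image); w <- ncol(image)
  chars <- strsplit(text, "")[[1]]
  x <- col
  for (ch in chars) {
    glyph <- font[[ch]]
    if (is.null(glyph)) glyph <- font[[" "]]
    for (gr in 1:5) {
      for (gc in 1:3) {
        if (glyph[gr, gc] == 1L) {
          rr <- row + gr - 1L; cc <- x + gc - 1L
          if (rr >= 1L && rr <= h && cc >= 1L && cc <= w) image[rr, cc] <- value
        }
      }
    }
    x <- x + 4L
  }
  image
}

#' Annotate an image with per-contour length labels
#'
#' Outlines each measurement's bounding box and stamps a small bitmap label
#' ("<sum_pixels>px" plus, when `cal` is given, "<length_cm>cm") adjacent to
#' the box — above it, or below when the box touches the top of the image.
#' Source pixels away from the annotation are unmodified.
#'
#' @param image 8-bit image matrix.
#' @param measurements data.frame from [label_contours()] /
#'   [measure_contours()].
#' @param cal optional [calibration_ratio()]; adds the cm value to labels.
#' @param value intensity for outlines/labels (default 255).
#' @return annotated image matrix with attribute `"labels"`: a data.frame
#'   (contour_id, anchor_row, anchor_col, text).
#' @export
annotate_lengths <- function(image, measurements, cal = NULL, value = 255) {
  h <- nrow(image); w <- ncol(image)
  if (nrow(measurements) == 0L) {
    attr(image, "labels") <- data.frame(contour_id = integer(),
                                        anchor_row = integer(),
                                        anchor_col = integer(),
                                        text = character())
    return(image)
  }
  if (any(measurements$row_min < 1 | measurements$col_min < 1 |
          measurements$row_max > h | measurements$col_max > w)) {
    stop("measurement bounding box outside image")
  }
  labels <- data.frame(contour_id = integer(), anchor_row = integer(),
                       anchor_col = integer(), text = character())
  for (i in seq_len(nrow(measurements))) {
    m <- measurements[i, ]
    rr <- m$row_min:m$row_max; cc <- m$col_min:m$col_max
    image[m$row_min, cc] <- value
    image[m$row_max, cc] <- value
    image[rr, m$col_min] <- value
    image[rr, m$col_max] <- value
    text <- sprintf("%dpx", m$sum_pixels)
    if (!is.null(cal)) {
      text <- sprintf("%s %.2fcm", text, measure_radicle(m$sum_pixels, cal))
    }
    anchor_row <- if (m$row_min >= 8L) m$row_min - 7L else m$row_max + 3L
    anchor_col <- max(1L, m$col_min)
    image <- stamp_text(image, anchor_row, anchor_col, text, value)
    labels <- rbind(labels, data.frame(contour_id = m$contour_id,
                                       anchor_row = anchor_row,
                                       anchor_col = anchor_col, text = text))
  }
  attr(image, "labels") <- labels
  image
}

#' Export contour measurements as CSV
#'
#' Columns: image_id, contour_id, sum_pixels, length_cm, centroid_row,
#' centroid_col. Exported pixel coordinates are 0-based (row-major, origin
#' top-left), i.e. the in-memory 1-based matrix indices minus 1.
#'
#' @param measurements data.frame from [measure_contours()].
#' @param path output CSV path.
#' @param image_id identifier recorded in the first column.
#' @export
write_measurements_csv <- function(measurements, path, image_id = "image") {
  out <- data.frame(image_id = rep(image_id, nrow(measurements)),
                    contour_id = measurements$contour_id,
                    sum_pixels = measurements$sum_pixels,
                    length_cm = measurements$length_cm,
                    centroid_row = measurements$centroid_row - 1,
                    centroid_col = measurements$centroid_col - 1)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
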