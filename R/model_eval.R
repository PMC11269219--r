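# Detection/segmentation evaluation arithmetic: IoU, average precision over
# IoU thresholds, convolution FLOPS/parameter counts, and machine-vs-manual
# agreement regression.

#' Intersection over union of two boxes
#'
#' Boxes are continuous half-open `(x_min, y_min, x_max, y_max)` with area
#' `(x_max - x_min) * (y_max - y_min)` (no +1 pixel convention).
#'
#' @param a,b numeric length-4 vectors.
#' @export
box_iou <- function(a, b) {
  for (bx in list(a, b)) {
    if (length(bx) != 4L || bx[1] >= bx[3] || bx[2] >= bx[4]) {
      stop("degenerate box: ", paste(bx, collapse = ","))
    }
  }
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

#' Intersection over union of two binary masks
#'
#' Defined as 1 when both masks are empty (empty union).
#'
#' @param a,b equal-size binary matrices.
#' @export
mask_iou <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("masks must have equal dimensions")
  a <- a != 0; b <- b != 0
  union <- sum(a | b)
  if (union == 0) return(1)
  sum(a & b) / union
}

#' @keywords internal
#' @noRd
pred_geoms <- function(x) {
  if (is.data.frame(x)) {
    lapply(seq_len(nrow(x)), function(i) {
      as.numeric(x[i, c("x_min", "y_min", "x_max", "y_max")])
    })
  } else if (is.list(x) && !is.null(x$masks)) {
    x$masks
  } else {
    stop("predictions/truths must be a box data.frame or list(masks=, confidence=)")
  }
}

#' Average precision at one IoU threshold (single class)
#'
#' Greedy matching in descending confidence: each prediction is matched to
#' the unmatched ground truth of highest IoU, counting as a true positive
#' when that IoU reaches the threshold; each truth is consumable once. AP is
#' the area under the precision-recall curve with all-points interpolation
#' (the precision envelope is made monotone non-increasing before
#' integration), which matches the continuous integral form exactly for
#' finite data.
#'
#' @param preds boxes as a data.frame with columns `x_min, y_min, x_max,
#'   y_max, confidence`, or masks as `list(masks = <list of matrices>,
#'   confidence = <numeric>)`.
#' @param truths boxes as a data.frame with the box columns, or
#'   `list(masks = ...)`.
#' @param iou_threshold matching threshold in (0, 1).
#' @return AP in `[0, 1]`, with attribute `"pr"`: the cumulative
#'   precision/recall table.
#' @export
average_precision <- function(preds, truths, iou_threshold = 0.5) {
  if (iou_threshold <= 0 || iou_threshold >= 1) {
    stop("iou_threshold must lie in (0, 1)")
  }
  tg <- pred_geoms(truths)
  n_t <- length(tg)
  if (n_t == 0L) stop("need at least one ground truth")
  pg <- pred_geoms(preds)
  conf <- if (is.data.frame(preds)) preds$confidence else preds$confidence
  if (length(pg) == 0L) {
    ap <- 0
    attr(ap, "pr") <- data.frame(precision = numeric(), recall = numeric())
    return(ap)
  }
  if (is.null(conf) || length(conf) != length(pg)) {
    stop("each prediction needs a confidence")
  }
  iou_fun <- if (is.data.frame(preds)) box_iou else mask_iou
  ord <- order(-conf)
  matched <- rep(FALSE, n_t)
  tp <- logical(length(pg))
  for (i in ord) {
    ious <- vapply(seq_len(n_t), function(j) {
      if (matched[j]) -1 else iou_fun(pg[[i]], tg[[j]])
    }, numeric(1))
    best <- which.max(ious)
    if (length(best) && ious[best] >= iou_threshold) {
      matched[best] <- TRUE
      tp[i] <- TRUE
    }
  }
  tp <- tp[ord]
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  recall <- cum_tp / n_t
  precision <- cum_tp / (cum_tp + cum_fp)
  # monotone precision envelope, integrated over recall steps
  env <- rev(cummax(rev(precision)))
  ap <- sum(diff(c(0, recall)) * env)
  attr(ap, "pr") <- data.frame(precision = precision, recall = recall)
  ap
}

#' AP over the 0.50:0.05:0.95 IoU threshold range
#'
#' Computes AP at the 10 thresholds 0.50, 0.55, ..., 0.95; `map50` is the AP
#' at 0.50 and `map50_95` their unweighted mean. When a `class_id` column is
#' present, AP is computed per class appearing in the truths and averaged
#' (the `1/n_c` factor); otherwise everything is one class.
#'
#' @inheritParams average_precision
#' @param thresholds IoU thresholds (default the canonical 10).
#' @return object of class `eval_result`: list with `per_threshold_ap`
#'   (named vector), `map50`, `map50_95`, `n_classes`, `pr_curve` (at the
#'   first threshold).
#' @export
map_range <- function(preds, truths, thresholds = seq(0.5, 0.95, by = 0.05)) {
  split_by_class <- function(x) {
    if (is.data.frame(x) && "class_id" %in% names(x)) {
      split(x, x$class_id)
    } else {
      list("0" = x)
    }
  }
  ts <- split_by_class(truths)
  ps <- split_by_class(preds)
  classes <- names(ts)
  empty_preds <- if (is.data.frame(preds)) preds[0, , drop = FALSE] else {
    list(masks = list(), confidence = numeric())
  }
  aps <- sapply(thresholds, function(th) {
    mean(vapply(classes, function(cl) {
      p <- ps[[cl]]
      if (is.null(p)) p <- empty_preds
      as.numeric(average_precision(p, ts[[cl]], th))
    }, numeric(1)))
  })
  names(aps) <- sprintf("%.2f", thresholds)
  p1 <- ps[[classes[1]]]
  if (is.null(p1)) p1 <- empty_preds
  pr <- attr(average_precision(p1, ts[[classes[1]]], thresholds[1]), "pr")
  structure(list(per_threshold_ap = aps, map50 = aps[["0.50"]],
                 map50_95 = mean(aps), n_classes = length(classes),
                 pr_curve = pr),
            class = "eval_result")
}

#' Convolution layer complexity
#'
#' Exact integer arithmetic for a `K x K` convolution over an `H x W`
#' feature map: `flops = 2 * H * W * (C_in * K^2 + 1) * C_out` (the +1 is
#' the bias add, the factor 2 counts multiply and accumulate separately) and
#' `params = C_in * K^2 * C_out`.
#'
#' @param H,W feature map height and width.
#' @param C_in,C_out input and output channel counts.
#' @param K kernel side length.
#' @return object of class `complexity_report`.
#' @export
conv_complexity <- function(H, W, C_in, K, C_out) {
  args <- c(H = H, W = W, C_in = C_in, K = K, C_out = C_out)
  if (any(args != round(args)) || any(args <= 0)) {
    stop("all inputs must be positive integers")
  }
  structure(list(H = H, W = W, C_in = C_in, C_out = C_out, K = K,
                 flops = 2 * H * W * (C_in * K^2 + 1) * C_out,
                 params = C_in * K^2 * C_out),
            class = "complexity_report")
}

#' Machine-vs-manual agreement analysis
#'
#' Ordinary least squares of machine-measured lengths on manual measurements
#' (`machine = slope * manual + intercept`), with `r_squared = 1 -
#' SS_res/SS_tot`, plus per-series summary statistics and the paired data
#' for distribution/beeswarm plots.
#'
#' @param machine_cm,manual_cm equal-length numeric vectors (cm), n >= 2.
#' @return object of class `agreement_report`: slope, intercept, r_squared,
#'   machine/manual summaries (mean, median, min, max), n, and `data`.
#' @export
agreement_analysis <- function(machine_cm, manual_cm) {
  if (length(machine_cm) != length(manual_cm) || length(machine_cm) < 2L) {
    stop("need equal-length series with at least 2 points")
  }
  if (!all(is.finite(machine_cm)) || !all(is.finite(manual_cm))) {
    stop("values must be finite")
  }
  if (stats::var(manual_cm) == 0) stop("manual series has zero variance")
  fit <- stats::lm(machine_cm ~ manual_cm)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((machine_cm - mean(machine_cm))^2)
  summ <- function(x) c(mean = mean(x), median = stats::median(x),
                        min = min(x), max = max(x))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
                 machine = summ(machine_cm), manual = summ(manual_cm),
                 n = length(machine_cm),
                 data = data.frame(manual_cm = manual_cm,
                                   machine_cm = machine_cm)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("machine = %.4f * manual + %.4f   (r^2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  cat(sprintf("machine: mean %.2f, median %.2f, range [%.2f, %.2f] cm\n",
              x$machine["mean"], x$machine["median"], x$machine["min"],
              x$machine["max"]))
  cat(sprintf("manual:  mean %.2f, median %.2f, range [%.2f, %.2f] cm\n",
              x$manual["mean"], x$manual["median"], x$manual["min"],
              x$manual["max"]))
  invisible(x)
}
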