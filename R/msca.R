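# Pure-numeric forward pass of a multi-scale convolutional attention (MSCA)
# block and its encoder's downsampling block. Feature maps are 3-D arrays
# indexed (channel, row, col); no training, just the arithmetic.

#' @keywords internal
#' @noRd
check_feature_map <- function(f) {
  if (!is.array(f) || length(dim(f)) != 3L) {
    stop("feature map must be a 3-D array (channel, row, col)")
  }
  if (!all(is.finite(f))) stop("feature map must be finite")
  f
}

#' @keywords internal
#' @noRd
per_channel_kernels <- function(kernels, n_channels) {
  if (is.matrix(kernels)) kernels <- rep(list(kernels), n_channels)
  if (!is.list(kernels) || length(kernels) != n_channels) {
    stop("need one kernel per channel (got ", length(kernels), " for ",
         n_channels, " channels)")
  }
  for (k in kernels) {
    if (nrow(k) %% 2L == 0L || ncol(k) %% 2L == 0L) {
      stop("kernel dimensions must be odd")
    }
  }
  kernels
}

#' Depthwise convolution
#'
#' Convolves each channel independently with its own kernel (reflection
#' padding, shape preserved). A single matrix kernel is recycled across
#' channels.
#'
#' @param f 3-D feature array (channel, row, col).
#' @param kernels list of odd-sized kernel matrices, one per channel, or a
#'   single matrix.
#' @export
depthwise_conv <- function(f, kernels) {
  check_feature_map(f)
  ch <- dim(f)[1]
  kernels <- per_channel_kernels(kernels, ch)
  out <- f
  for (c in seq_len(ch)) {
    out[c, , ] <- conv2_reflect(f[c, , ], kernels[[c]])
  }
  out
}

#' Strip-convolution branch
#'
#' Applies a separable large-kernel approximation: a `1 x k` depthwise pass
#' followed by a `k x 1` depthwise pass. Equivalent to depthwise convolution
#' with the dense `k x k` outer-product kernel.
#'
#' @param f 3-D feature array.
#' @param kernel_h `1 x k` kernel (matrix or per-channel list).
#' @param kernel_v `k x 1` kernel (matrix or per-channel list).
#' @export
strip_branch <- function(f, kernel_h, kernel_v) {
  check_feature_map(f)
  ch <- dim(f)[1]
  kh <- per_channel_kernels(kernel_h, ch)
  kv <- per_channel_kernels(kernel_v, ch)
  for (c in seq_len(ch)) {
    if (nrow(kh[[c]]) != 1L || ncol(kv[[c]]) != 1L) {
      stop("strip kernels must be 1 x k and k x 1")
    }
  }
  depthwise_conv(depthwise_conv(f, kh), kv)
}

#' MSCA weight container
#'
#' Bundles the weights of one MSCA block: the local-aggregation depthwise
#' kernel (5 x 5 by default), one separable kernel pair per strip-convolution
#' scale (defaults approximate 7x7, 11x11 and 21x21 kernels), and the 1x1
#' channel-mixing matrix.
#'
#' @param dw_kernel depthwise aggregation kernel (matrix or per-channel
#'   list).
#' @param branch_kernels list over scales; each element
#'   `list(h = 1 x k, v = k x 1)` (matrices or per-channel lists).
#' @param mix_1x1 square `C x C` channel-mixing matrix.
#' @export
msca_weights <- function(dw_kernel, branch_kernels, mix_1x1) {
  if (!is.matrix(mix_1x1) || nrow(mix_1x1) != ncol(mix_1x1)) {
    stop("mix_1x1 must be a square matrix for the gating product to be defined")
  }
  structure(list(dw_kernel = dw_kernel, branch_kernels = branch_kernels,
                 mix_1x1 = mix_1x1),
            class = "msca_weights")
}

#' Deterministic random MSCA weights for testing
#'
#' @param n_channels channel count C.
#' @param scales strip-convolution scales (odd).
#' @param dw_size depthwise aggregation kernel side.
#' @param rng_seed integer seed; generation is bit-reproducible.
#' @export
random_msca_weights <- function(n_channels, scales = c(7L, 11L, 21L),
                                dw_size = 5L, rng_seed = 1L) {
  if (any(scales %% 2L == 0L)) stop("scales must be odd")
  withr::with_seed(rng_seed, {
    dw <- lapply(seq_len(n_channels), function(i) {
      matrix(stats::rnorm(dw_size^2, sd = 1 / dw_size), dw_size, dw_size)
    })
    branches <- lapply(scales, function(k) {
      list(h = lapply(seq_len(n_channels), function(i) {
             matrix(stats::rnorm(k, sd = 1 / sqrt(k)), 1L, k)
           }),
           v = lapply(seq_len(n_channels), function(i) {
             matrix(stats::rnorm(k, sd = 1 / sqrt(k)), k, 1L)
           }))
    })
    mix <- matrix(stats::rnorm(n_channels^2, sd = 1 / sqrt(n_channels)),
                  n_channels, n_channels)
    msca_weights(dw, branches, mix)
  })
}

#' MSCA forward pass
#'
#' Computes `base = DWConv(F)`, sums branch 0 (a skip connection that
#' contributes `base` itself) with the strip-convolution branches applied to
#' `base`, mixes channels with the 1x1 matrix to form the attention map
#' `Att`, and gates the input elementwise: `Out = Att * F`. No nonlinearity
#' is applied. Since `Att` is linear in `F`, the output is homogeneous of
#' degree 2 in the input.
#'
#' @param f 3-D feature array (channel, row, col).
#' @param w an [msca_weights()] whose mixing matrix matches `f`'s channels.
#' @return gated feature array, same shape as `f`.
#' @export
msca_forward <- function(f, w) {
  check_feature_map(f)
  stopifnot(inherits(w, "msca_weights"))
  ch <- dim(f)[1]
  if (nrow(w$mix_1x1) != ch) {
    stop("mix_1x1 is ", nrow(w$mix_1x1), "x", ncol(w$mix_1x1),
         " but the feature map has ", ch, " channels")
  }
  base <- depthwise_conv(f, w$dw_kernel)
  s <- base
  for (b in w$branch_kernels) {
    s <- s + strip_branch(base, b$h, b$v)
  }
  sm <- matrix(s, nrow = ch)                # (C, H*W), channel-major
  att <- array(w$mix_1x1 %*% sm, dim = dim(f))
  att * f
}

#' Batch-normalization statistics
#'
#' @param mean,variance,gain,bias per-channel numeric vectors.
#' @param epsilon small positive stabiliser.
#' @export
bn_stats <- function(mean, variance, gain = rep(1, length(mean)),
                     bias = rep(0, length(mean)), epsilon = 1e-5) {
  if (any(variance < 0)) stop("variance must be non-negative")
  structure(list(mean = mean, variance = variance, gain = gain, bias = bias,
                 epsilon = epsilon),
            class = "bn_stats")
}

#' Encoder downsampling block: strided 3x3 convolution + batch norm
#'
#' A 3x3 convolution with stride 2 and (reflection) padding 1 — output
#' spatial dims `ceil(H/2) x ceil(W/2)` — followed by per-channel
#' normalization `(x - mean) / sqrt(var + eps) * gain + bias`.
#'
#' @param f 3-D feature array (C_in, H, W).
#' @param weights 4-D array `(C_out, C_in, 3, 3)`.
#' @param bn a [bn_stats()] with one entry per output channel, or NULL to
#'   skip normalization.
#' @return feature array `(C_out, ceil(H/2), ceil(W/2))`.
#' @export
mscan_downsample <- function(f, weights, bn = NULL) {
  check_feature_map(f)
  if (!is.array(weights) || length(dim(weights)) != 4L ||
      dim(weights)[3] != 3L || dim(weights)[4] != 3L) {
    stop("weights must be a (C_out, C_in, 3, 3) array")
  }
  c_in <- dim(f)[1]
  if (dim(weights)[2] != c_in) {
    stop("weights expect ", dim(weights)[2], " input channels, got ", c_in)
  }
  c_out <- dim(weights)[1]
  h <- dim(f)[2]; w <- dim(f)[3]
  ri <- seq(1L, h, by = 2L); ci <- seq(1L, w, by = 2L)
  out <- array(0, dim = c(c_out, length(ri), length(ci)))
  for (o in seq_len(c_out)) {
    acc <- matrix(0, h, w)
    for (i in seq_len(c_in)) {
      acc <- acc + conv2_reflect(f[i, , ], matrix(weights[o, i, , ], 3L, 3L))
    }
    out[o, , ] <- acc[ri, ci, drop = FALSE]
  }
  if (!is.null(bn)) {
    stopifnot(inherits(bn, "bn_stats"), length(bn$mean) == c_out)
    for (o in seq_len(c_out)) {
      out[o, , ] <- (out[o, , ] - bn$mean[o]) / sqrt(bn$variance[o] + bn$epsilon) *
        bn$gain[o] + bn$bias[o]
    }
  }
  out
}

#' One encoder stage: downsample then a stack of MSCA blocks
#'
#' Composition helper for the 4-stage encoder layout (each stage halves the
#' spatial resolution, then applies MSCA blocks with user-supplied weights).
#'
#' @param f input feature array.
#' @param down_weights `(C_out, C_in, 3, 3)` array for [mscan_downsample()].
#' @param bn a [bn_stats()] (or NULL).
#' @param blocks list of [msca_weights()] applied in order after
#'   downsampling.
#' @export
mscan_stage <- function(f, down_weights, bn = NULL, blocks = list()) {
  out <- mscan_downsample(f, down_weights, bn)
  for (w in blocks) out <- msca_forward(out, w)
  out
}

#' Read / write MSCA weights as a compressed archive of named arrays
#'
#' Serialises the weight container to a single gzip-compressed RDS file.
#'
#' @param w an [msca_weights()].
#' @param path file path.
#' @export
write_msca_weights <- function(w, path) {
  stopifnot(inherits(w, "msca_weights"))
  saveRDS(unclass(w), path, compress = "gzip")
  invisible(path)
}

#' @rdname write_msca_weights
#' @export
read_msca_weights <- function(path) {
  x <- readRDS(path)
  msca_weights(x$dw_kernel, x$branch_kernels, x$mix_1x1)
}
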