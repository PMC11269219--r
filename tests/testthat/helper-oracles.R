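# Independent oracles, written as straightforward loops so they share no
# code path with the package implementation.

# -- reference Canny chain ---------------------------------------------------

ref_reflect <- function(i, n) {
  repeat {
    if (i < 1L) i <- 1L - i
    else if (i > n) i <- 2L * n + 1L - i
    else return(i)
  }
}

ref_gaussian <- function(img, sigma, ks) {
  r <- (ks - 1L) %/% 2L
  k <- matrix(0, ks, ks)
  for (i in seq_len(ks)) for (j in seq_len(ks)) {
    k[i, j] <- exp(-((i - r - 1L)^2 + (j - r - 1L)^2) / (2 * sigma^2))
  }
  k <- k / sum(k)
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    s <- 0
    for (i in seq_len(ks)) for (j in seq_len(ks)) {
      s <- s + k[i, j] * img[ref_reflect(y + i - r - 1L, h),
                             ref_reflect(x + j - r - 1L, w)]
    }
    out[y, x] <- s
  }
  out
}

ref_sobel <- function(img) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  ky <- t(kx)
  h <- nrow(img); w <- ncol(img)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    sx <- 0; sy <- 0
    for (i in 1:3) for (j in 1:3) {
      v <- img[ref_reflect(y + i - 2L, h), ref_reflect(x + j - 2L, w)]
      sx <- sx + kx[i, j] * v
      sy <- sy + ky[i, j] * v
    }
    gx[y, x] <- sx; gy[y, x] <- sy
  }
  list(mag = sqrt(gx^2 + gy^2), dir = atan2(gy, gx))
}

ref_nms <- function(mag, dir) {
  h <- nrow(mag); w <- ncol(mag)
  out <- matrix(0, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    d <- (dir[y, x] * 180 / pi) %% 180
    if (d < 22.5 || d >= 157.5) off <- c(0L, 1L)
    else if (d < 67.5) off <- c(1L, 1L)
    else if (d < 112.5) off <- c(1L, 0L)
    else off <- c(1L, -1L)
    getm <- function(r, c) {
      if (r < 1L || r > h || c < 1L || c > w) 0 else mag[r, c]
    }
    a <- getm(y + off[1], x + off[2])
    b <- getm(y - off[1], x - off[2])
    if (mag[y, x] >= a && mag[y, x] >= b) out[y, x] <- mag[y, x]
  }
  out
}

# hysteresis by repeated dilation from strong seeds (independent of the
# sparse graph labeling route)
ref_hysteresis <- function(thinned, low, high) {
  h <- nrow(thinned); w <- ncol(thinned)
  edges <- thinned >= high
  cand <- thinned >= low
  repeat {
    changed <- FALSE
    for (y in seq_len(h)) for (x in seq_len(w)) {
      if (!edges[y, x] && cand[y, x]) {
        for (dy in -1:1) for (dx in -1:1) {
          r <- y + dy; c <- x + dx
          if (r >= 1L && r <= h && c >= 1L && c <= w && edges[r, c]) {
            edges[y, x] <- TRUE; changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  out <- matrix(0L, h, w)
  out[edges] <- 1L
  out
}

ref_canny <- function(img, sigma, ks, low, high) {
  sm <- ref_gaussian(img, sigma, ks)
  g <- ref_sobel(sm)
  ref_hysteresis(ref_nms(g$mag, g$dir), low, high)
}

# -- flood-fill component oracle (8-connected) -------------------------------

ff_label <- function(binary) {
  h <- nrow(binary); w <- ncol(binary)
  lab <- matrix(0L, h, w)
  nextl <- 0L
  for (y0 in seq_len(h)) for (x0 in seq_len(w)) {
    if (binary[y0, x0] != 0 && lab[y0, x0] == 0L) {
      nextl <- nextl + 1L
      stack <- list(c(y0, x0))
      lab[y0, x0] <- nextl
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (dy in -1:1) for (dx in -1:1) {
          r <- p[1] + dy; c <- p[2] + dx
          if (r >= 1L && r <= h && c >= 1L && c <= w &&
              binary[r, c] != 0 && lab[r, c] == 0L) {
            lab[r, c] <- nextl
            stack[[length(stack) + 1L]] <- c(r, c)
          }
        }
      }
    }
  }
  lab
}

# -- naive convolution oracles (MSCA) ----------------------------------------

naive_depthwise <- function(f, kernels) {
  ch <- dim(f)[1]; h <- dim(f)[2]; w <- dim(f)[3]
  if (is.matrix(kernels)) kernels <- rep(list(kernels), ch)
  out <- array(0, dim(f))
  for (cc in seq_len(ch)) {
    k <- kernels[[cc]]
    kh <- nrow(k); kw <- ncol(k)
    rh <- (kh - 1L) %/% 2L; rw <- (kw - 1L) %/% 2L
    for (y in seq_len(h)) for (x in seq_len(w)) {
      s <- 0
      for (i in seq_len(kh)) for (j in seq_len(kw)) {
        s <- s + k[i, j] * f[cc, ref_reflect(y + i - rh - 1L, h),
                             ref_reflect(x + j - rw - 1L, w)]
      }
      out[cc, y, x] <- s
    }
  }
  out
}

naive_msca <- function(f, w) {
  ch <- dim(f)[1]
  base <- naive_depthwise(f, w$dw_kernel)
  s <- base
  for (b in w$branch_kernels) {
    kh <- b$h; kv <- b$v
    if (is.matrix(kh)) kh <- rep(list(kh), ch)
    if (is.matrix(kv)) kv <- rep(list(kv), ch)
    dense <- lapply(seq_len(ch), function(cc) kv[[cc]] %*% kh[[cc]])
    s <- s + naive_depthwise(base, dense)
  }
  att <- array(0, dim(f))
  for (o in seq_len(ch)) for (cc in seq_len(ch)) {
    att[o, , ] <- att[o, , ] + w$mix_1x1[o, cc] * s[cc, , ]
  }
  att * f
}

naive_downsample <- function(f, weights, bn = NULL) {
  c_in <- dim(f)[1]; h <- dim(f)[2]; w <- dim(f)[3]
  c_out <- dim(weights)[1]
  oh <- ceiling(h / 2); ow <- ceiling(w / 2)
  out <- array(0, dim = c(c_out, oh, ow))
  for (o in seq_len(c_out)) for (y in seq_len(oh)) for (x in seq_len(ow)) {
    s <- 0
    for (cc in seq_len(c_in)) for (i in 1:3) for (j in 1:3) {
      s <- s + weights[o, cc, i, j] *
        f[cc, ref_reflect(2L * y - 2L + i - 1L, h),
          ref_reflect(2L * x - 2L + j - 1L, w)]
    }
    out[o, y, x] <- s
  }
  if (!is.null(bn)) {
    for (o in seq_len(c_out)) {
      out[o, , ] <- (out[o, , ] - bn$mean[o]) / sqrt(bn$variance[o] + bn$epsilon) *
        bn$gain[o] + bn$bias[o]
    }
  }
  out
}

# -- brute-force PR / AP oracle ----------------------------------------------

brute_ap <- function(boxes_pred, conf, boxes_truth, thr) {
  n_p <- nrow(boxes_pred); n_t <- nrow(boxes_truth)
  iou <- function(a, b) {
    iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
    ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
    inter <- iw * ih
    inter / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter)
  }
  ord <- order(conf, decreasing = TRUE)
  used <- rep(FALSE, n_t)
  tp <- numeric(0); fp <- numeric(0)
  for (i in ord) {
    best <- 0; best_j <- 0L
    for (j in seq_len(n_t)) {
      if (!used[j]) {
        v <- iou(as.numeric(boxes_pred[i, ]), as.numeric(boxes_truth[j, ]))
        if (v > best) { best <- v; best_j <- j }
      }
    }
    if (best_j > 0L && best >= thr) {
      used[best_j] <- TRUE
      tp <- c(tp, 1); fp <- c(fp, 0)
    } else {
      tp <- c(tp, 0); fp <- c(fp, 1)
    }
  }
  ctp <- cumsum(tp); cfp <- cumsum(fp)
  rec <- ctp / n_t
  prec <- ctp / (ctp + cfp)
  ap <- 0; prev_r <- 0
  for (i in seq_along(rec)) {
    p_max <- max(prec[i:length(prec)])
    ap <- ap + (rec[i] - prev_r) * p_max
    prev_r <- rec[i]
  }
  ap
}

# -- small synthetic helpers -------------------------------------------------

random_binary <- function(h, w, p = 0.3) {
  matrix(as.integer(stats::runif(h * w) < p), h, w)
}
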