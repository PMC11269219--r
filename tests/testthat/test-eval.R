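test_that("IoU arithmetic on boxes and masks", {
  expect_equal(box_iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(box_iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  # unit squares overlapping by half: 0.5 / 1.5
  expect_equal(box_iou(c(0, 0, 1, 1), c(0.5, 0, 1.5, 1)), 1 / 3)
  expect_error(box_iou(c(0, 0, 0, 1), c(0, 0, 1, 1)), "degenerate")

  a <- matrix(0L, 4, 4); a[1:2, 1:2] <- 1L
  b <- matrix(0L, 4, 4); b[2:3, 2:3] <- 1L
  expect_equal(mask_iou(a, b), 1 / 7)
  expect_equal(mask_iou(matrix(0L, 3, 3), matrix(0L, 3, 3)), 1)
  expect_error(mask_iou(a, matrix(0L, 5, 5)), "equal dimensions")
})

perfect_fixture <- function() {
  truths <- data.frame(x_min = c(0, 20, 50), y_min = c(0, 20, 5),
                       x_max = c(10, 30, 60), y_max = c(10, 30, 15))
  preds <- cbind(truths, confidence = c(0.9, 0.8, 0.95))
  list(preds = preds, truths = truths)
}

test_that("perfect predictions give AP 1 at every threshold", {
  fx <- perfect_fixture()
  res <- map_range(fx$preds, fx$truths)
  expect_length(res$per_threshold_ap, 10)
  expect_equal(names(res$per_threshold_ap)[c(1, 10)], c("0.50", "0.95"))
  expect_true(all(res$per_threshold_ap == 1))
  expect_equal(res$map50_95, 1)

  none <- fx$preds[0, ]
  expect_equal(as.numeric(average_precision(none, fx$truths, 0.5)), 0)
  expect_error(average_precision(fx$preds, fx$truths[0, ], 0.5), "ground truth")
  expect_error(average_precision(fx$preds, fx$truths, 1.5), "in \\(0, 1\\)")
})

test_that("3-prediction/2-truth case matches hand enumeration at every threshold", {
  truths <- data.frame(x_min = c(0, 20), y_min = c(0, 20),
                       x_max = c(10, 30), y_max = c(10, 30))
  preds <- data.frame(x_min = c(0, 21, 40), y_min = c(0, 21, 40),
                      x_max = c(10, 31, 50), y_max = c(10, 31, 50),
                      confidence = c(0.9, 0.8, 0.7))
  # P1 matches T1 with IoU 1; P2 matches T2 with IoU 81/119 ~ 0.6807;
  # P3 matches nothing. By hand: for thr <= 0.6807 the PR sequence is
  # TP,TP,FP -> precision (1, 1, 2/3), recall (.5, 1, 1) -> AP 1;
  # for thr > 0.6807: TP,FP,FP -> AP 0.5.
  res <- map_range(preds, truths)
  expect_equal(unname(res$per_threshold_ap),
               c(1, 1, 1, 1, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5))
  expect_equal(res$map50_95, 0.7)
  expect_equal(res$map50, 1)
  # and against the brute-force oracle at each threshold
  for (th in seq(0.5, 0.95, by = 0.05)) {
    expect_equal(as.numeric(average_precision(preds, truths, th)),
                 brute_ap(preds[, 1:4], preds$confidence, truths, th))
  }
})

test_that("AP matches the brute-force oracle on random cases and is rank-invariant", {
  set.seed(71)
  for (rep in 1:10) {
    n_t <- sample(1:4, 1); n_p <- sample(0:6, 1)
    truths <- data.frame(x_min = stats::runif(n_t, 0, 50),
                         y_min = stats::runif(n_t, 0, 50))
    truths$x_max <- truths$x_min + stats::runif(n_t, 5, 15)
    truths$y_max <- truths$y_min + stats::runif(n_t, 5, 15)
    preds <- data.frame(x_min = stats::runif(n_p, 0, 50),
                        y_min = stats::runif(n_p, 0, 50))
    if (n_p > 0) {
      preds$x_max <- preds$x_min + stats::runif(n_p, 5, 15)
      preds$y_max <- preds$y_min + stats::runif(n_p, 5, 15)
      preds$confidence <- sample(seq(0.05, 0.95, by = 0.05), n_p)
    } else {
      preds$x_max <- preds$y_max <- preds$confidence <- numeric(0)
    }
    for (th in c(0.3, 0.5, 0.75)) {
      got <- as.numeric(average_precision(preds, truths, th))
      expect_equal(got, brute_ap(preds[, c("x_min", "y_min", "x_max", "y_max")],
                                 preds$confidence, truths, th))
    }
    if (n_p > 0) {
      # monotone rescaling of confidences leaves AP unchanged
      resc <- preds
      resc$confidence <- stats::plogis(5 * preds$confidence - 1)
      expect_equal(as.numeric(average_precision(resc, truths, 0.5)),
                   as.numeric(average_precision(preds, truths, 0.5)))
      res <- map_range(preds, truths)
      expect_lte(res$map50_95, res$map50 + 1e-12)
    }
  }
})

test_that("mask-based AP agrees with equivalent box geometry", {
  mk <- function(r, c) { m <- matrix(0L, 20, 20); m[r, c] <- 1L; m }
  truths <- list(masks = list(mk(1:5, 1:5), mk(10:14, 10:14)))
  preds <- list(masks = list(mk(1:5, 1:5), mk(10:14, 11:15)),
                confidence = c(0.9, 0.8))
  ap <- as.numeric(average_precision(preds, truths, 0.5))
  # second mask overlaps 4/6 columns of 5: IoU = 20/30 = 2/3 >= 0.5 -> both TP
  expect_equal(ap, 1)
  expect_equal(as.numeric(average_precision(preds, truths, 0.7)), 0.5)
})

test_that("convolution complexity follows the exact closed forms", {
  r <- conv_complexity(1, 1, 1, 1, 1)
  expect_identical(c(r$flops, r$params), c(4, 1))
  r <- conv_complexity(10, 10, 3, 3, 8)
  expect_identical(r$flops, 44800)
  expect_identical(r$params, 216)
  expect_error(conv_complexity(0, 10, 3, 3, 8), "positive integers")

  # flops equals 2x the counted multiply-accumulates of a naive biased conv
  count_macs <- function(H, W, C_in, K, C_out) {
    macs <- 0L
    for (o in seq_len(C_out)) for (y in seq_len(H)) for (x in seq_len(W)) {
      for (ci in seq_len(C_in)) for (i in seq_len(K)) for (j in seq_len(K)) {
        macs <- macs + 1L  # one multiply-add against the kernel
      }
      macs <- macs + 1L    # bias add (counted as one MAC slot)
    }
    macs
  }
  for (case in list(c(2, 3, 2, 3, 2), c(4, 4, 1, 1, 3))) {
    r <- conv_complexity(case[1], case[2], case[3], case[4], case[5])
    expect_equal(r$flops, 2 * count_macs(case[1], case[2], case[3], case[4], case[5]))
  }
})

test_that("agreement regression recovers exact and noisy relationships", {
  x <- seq(0.5, 5.2, length.out = 30)
  same <- agreement_analysis(x, x)
  expect_equal(same$slope, 1)
  expect_equal(same$intercept, 0)
  expect_equal(same$r_squared, 1)

  y <- 0.9737 * x - 0.0310
  rep <- agreement_analysis(y, x)
  expect_equal(rep$slope, 0.9737, tolerance = 1e-12)
  expect_equal(rep$intercept, -0.0310, tolerance = 1e-12)
  expect_equal(rep$r_squared, 1, tolerance = 1e-12)

  set.seed(81)
  noisy <- 0.95 * x + 0.1 + stats::rnorm(30, sd = 0.15)
  got <- agreement_analysis(noisy, x)
  # closed-form normal equations as the oracle
  sb <- sum((x - mean(x)) * (noisy - mean(noisy))) / sum((x - mean(x))^2)
  ib <- mean(noisy) - sb * mean(x)
  expect_equal(got$slope, sb, tolerance = 1e-10)
  expect_equal(got$intercept, ib, tolerance = 1e-10)
  pred <- sb * x + ib
  r2 <- 1 - sum((noisy - pred)^2) / sum((noisy - mean(noisy))^2)
  expect_equal(got$r_squared, r2, tolerance = 1e-10)

  expect_equal(got$machine[["median"]], stats::median(noisy))
  expect_error(agreement_analysis(c(1, 2), c(3, 3)), "zero variance")
})
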