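# Engine-level oracles ------------------------------------------------------

test_that("im2col convolution matches a direct sliding-dot-product oracle", {
  set.seed(21)
  H <- 7L; W <- 9L; C <- 2L; kh <- 3L; kw <- 3L; stride <- 2L; pad <- 1L
  x <- array(rnorm(H * W * C), c(H, W, C))
  f <- 4L
  Wm <- matrix(rnorm(kh * kw * C * f), kh * kw * C, f)
  cols <- massContext:::.im2col_cpp(x, kh, kw, stride, pad)
  oH <- (H + 2L * pad - kh) %/% stride + 1L
  oW <- (W + 2L * pad - kw) %/% stride + 1L
  out <- array(crossprod(cols, Wm), c(oH, oW, f))
  # independent oracle: explicit loops over output positions and taps
  oracle <- array(0, c(oH, oW, f))
  for (ff in 1:f) for (oi in 1:oH) for (oj in 1:oW) {
    acc <- 0
    for (c in 1:C) for (dj in 1:kw) for (di in 1:kh) {
      i <- (oi - 1L) * stride - pad + di
      j <- (oj - 1L) * stride - pad + dj
      if (i >= 1 && i <= H && j >= 1 && j <= W)
        acc <- acc + x[i, j, c] * Wm[(di - 1) + kh * ((dj - 1) + kw * (c - 1)) + 1, ff]
    }
    oracle[oi, oj, ff] <- acc
  }
  expect_equal(out, oracle, tolerance = 1e-12)
})

test_that("max pooling matches a direct oracle and routes gradients to argmax", {
  set.seed(22)
  x <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  r <- massContext:::.maxpool_fwd_cpp(x, 2L, 2L, 2L, 0L)
  oracle <- array(0, c(3, 3, 3))
  for (c in 1:3) for (oi in 1:3) for (oj in 1:3)
    oracle[oi, oj, c] <- max(x[(2 * oi - 1):(2 * oi), (2 * oj - 1):(2 * oj), c])
  expect_equal(r$out, oracle)
  dout <- array(1, c(3, 3, 3))
  dx <- massContext:::.maxpool_bwd_cpp(dout, r$argmax, 6L, 6L)
  expect_equal(sum(dx), sum(dout))          # gradient mass conserved
  expect_true(all(dx[dx != 0] == 1))
  expect_equal(sum(dx != 0), 27)            # one winner per window
})

test_that("analytic gradients agree with finite differences on the tiny net", {
  set.seed(23)
  m <- buildBackbone("tiny")
  x <- array(runif(32 * 32), c(32, 32, 1))
  target <- 2L
  fw <- massContext:::nnForward(m, x, keepCache = TRUE)
  bw <- massContext:::nnBackward(m, fw, target)
  lossAt <- function(model) {
    p <- massContext:::nnForward(model, x)$probs
    -log(max(p[target], 1e-12))
  }
  eps <- 1e-5
  for (id in c("c1", "c3", "fc")) {
    g <- bw$grads[[id]]$W
    ix <- sample(length(g), 3L)
    for (k in ix) {
      m2 <- m; m2@weights[[id]]$W[k] <- m2@weights[[id]]$W[k] + eps
      m3 <- m; m3@weights[[id]]$W[k] <- m3@weights[[id]]$W[k] - eps
      num <- (lossAt(m2) - lossAt(m3)) / (2 * eps)
      expect_equal(g[k], num, tolerance = 1e-3)
    }
  }
})

# Backbone contracts ---------------------------------------------------------

test_that("tiny backbone emits normalized probability pairs deterministically", {
  set.seed(24)
  m <- buildBackbone("tiny")
  rois <- replicate(3, matrix(runif(224 * 224, 0, 255), 224, 224),
                    simplify = FALSE)
  p <- predictProba(m, rois)
  expect_equal(dim(p), c(3L, 2L))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  expect_identical(p, predictProba(m, rois))
  # identical ROIs give identical pairs
  p2 <- predictProba(m, list(rois[[1]], rois[[1]]))
  expect_identical(p2[1, ], p2[2, ])
  expect_error(predictProba(m, list()), "no ROIs")
})

test_that("fine-tuning learns a separable patch set and respects the config", {
  sp <- separablePatches(nPerClass = 40L)
  m <- buildBackbone("tiny")
  cfg <- trainConfig(epochs = 5L, batchSize = 16L, learningRate = 0.05,
                     seed = 3L)
  m2 <- fineTune(m, sp$rois, sp$labels, cfg)
  log <- trainingLog(m2)
  expect_gt(max(log$train_acc), 0.9)
  expect_true(m2@trained)
  # zero epochs: weights unchanged
  m0 <- fineTune(m, sp$rois, sp$labels, trainConfig(epochs = 0L, seed = 3L))
  expect_identical(m0@weights, m@weights)
  # same seed twice: identical training curves
  m3 <- fineTune(m, sp$rois, sp$labels, cfg)
  expect_identical(trainingLog(m2), trainingLog(m3))
  # single-class data rejected
  expect_error(fineTune(m, sp$rois[1:10], rep("benign", 10), cfg), "both classes")
})

test_that("validation split is stratified and honored by early stopping bookkeeping", {
  sp <- separablePatches(nPerClass = 30L, size = 40L)
  m <- buildBackbone("tiny")
  m2 <- fineTune(m, sp$rois, sp$labels,
                 trainConfig(epochs = 2L, batchSize = 8L, learningRate = 0.02,
                             seed = 9L))
  log <- trainingLog(m2)
  expect_equal(nrow(log), 2L)
  expect_named(log, c("epoch", "train_loss", "val_loss", "train_acc", "val_acc"))
  expect_true(all(is.finite(unlist(log))))
})
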