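# Loss functions and segmentation metrics.

test_that("dice loss limits and closed forms", {
  g <- matrix(c(1, 1, 0, 0), 2)
  expect_equal(diceLoss(g, g, epsilon = 1e-12), 0, tolerance = 1e-9)
  p_disjoint <- 1 - g
  expect_equal(diceLoss(p_disjoint, g, epsilon = 1e-12), 1, tolerance = 1e-9)
  # p = 0.5 everywhere on a mask with k of n foreground pixels:
  # loss -> 1 - k / (n/2 + k)
  set.seed(71)
  n <- 64; k <- 24
  g2 <- matrix(0, 8, 8); g2[sample(n, k)] <- 1
  p2 <- matrix(0.5, 8, 8)
  expect_equal(diceLoss(p2, g2, epsilon = 1e-12), 1 - k / (n / 2 + k),
               tolerance = 1e-9)
  # elementwise-sum oracle on a random case
  p3 <- matrix(runif(n), 8); g3 <- (matrix(runif(n), 8) > 0.5) * 1
  num <- 0; dns <- 0
  for (i in seq_len(n)) { num <- num + p3[i] * g3[i]; dns <- dns + p3[i] + g3[i] }
  expect_equal(diceLoss(p3, g3, 1), 1 - (2 * num + 1) / (dns + 1),
               tolerance = 1e-12)
  expect_error(diceLoss(p3, g3[1:4, ]), "shape")
  expect_error(diceLoss(p3 + 2, g3), "probabilities")
})

test_that("bce loss closed forms and logit stability", {
  g <- (matrix(runif(64), 8) > 0.3) * 1
  expect_equal(bceLoss(matrix(0.5, 8, 8), g), log(2), tolerance = 1e-12)
  expect_lt(bceLoss(g, g), 2e-6)          # perfect probabilities, clamped
  # brute-force elementwise oracle
  set.seed(72)
  p <- matrix(runif(64, 0.01, 0.99), 8)
  acc <- 0
  for (i in seq_len(64))
    acc <- acc - (g[i] * log(p[i]) + (1 - g[i]) * log(1 - p[i]))
  expect_equal(bceLoss(p, g), acc / 64, tolerance = 1e-7)
  # logit form agrees with probability form and survives huge logits
  z <- matrix(rnorm(64, sd = 3), 8)
  expect_equal(bceLoss(z, g, from_logits = TRUE),
               bceLoss(1 / (1 + exp(-z)), g), tolerance = 1e-6)
  expect_true(is.finite(bceLoss(matrix(1000, 8, 8), g, from_logits = TRUE)))
})

test_that("total loss is the stated affine combination", {
  set.seed(73)
  p <- matrix(runif(36), 6); g <- (matrix(runif(36), 6) > 0.5) * 1
  expect_equal(totalLoss(p, g, lossWeights(1, 0)), bceLoss(p, g))
  expect_equal(totalLoss(p, g, lossWeights(0, 1)), diceLoss(p, g, 1))
  w <- lossWeights()                       # defaults alpha = beta = 1
  expect_equal(w$alpha, 1); expect_equal(w$beta, 1)
  l11 <- totalLoss(p, g, lossWeights(1, 1))
  l23 <- totalLoss(p, g, lossWeights(2, 3))
  expect_equal(l23, 2 * bceLoss(p, g) + 3 * diceLoss(p, g, 1),
               tolerance = 1e-12)
  expect_equal(l11, bceLoss(p, g) + diceLoss(p, g, 1), tolerance = 1e-12)
  expect_error(lossWeights(-1, 1), "non-negative")
})

test_that("metrics match the hand-counted contingency table", {
  # 4x4 toy: 4 true, 4 predicted, 2 overlapping
  g <- matrix(0, 4, 4); g[1, 1:4] <- 1
  pred <- matrix(0, 4, 4); pred[1, 1:2] <- 1; pred[2, 1:2] <- 1
  m <- segMetrics(pred, g)
  expect_equal(m$TP, 2); expect_equal(m$FP, 2); expect_equal(m$FN, 2)
  expect_equal(m$dice, 0.5)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$iou_fg, 1 / 3)
  # perfect prediction
  mp <- segMetrics(g, g)
  expect_equal(unlist(mp[c("dice", "precision", "recall", "miou")]),
               c(dice = 1, precision = 1, recall = 1, miou = 1))
  # empty prediction vs non-empty truth
  me <- segMetrics(g * 0, g)
  expect_equal(me$recall, 0); expect_equal(me$dice, 0)
  # both empty: defined as 1
  mb <- segMetrics(g * 0, g * 0)
  expect_equal(mb$dice, 1); expect_equal(mb$miou, 1)
  expect_error(segMetrics(pred * 0.5, g), "binary")
})

test_that("dice dominates foreground IoU on random mask pairs", {
  set.seed(74)
  for (i in 1:25) {
    a <- (matrix(runif(100), 10) > runif(1)) * 1
    b <- (matrix(runif(100), 10) > runif(1)) * 1
    m <- segMetrics(a, b)
    expect_gte(m$dice + 1e-12, m$iou_fg)
    # monotone identity dice = 2 IoU / (1 + IoU)
    expect_equal(m$dice, 2 * m$iou_fg / (1 + m$iou_fg), tolerance = 1e-12)
  }
})

test_that("mIoU is symmetric under foreground/background relabeling", {
  set.seed(75)
  a <- (matrix(runif(64), 8) > 0.4) * 1
  b <- (matrix(runif(64), 8) > 0.6) * 1
  expect_equal(segMetrics(a, b)$miou, segMetrics(1 - a, 1 - b)$miou,
               tolerance = 1e-12)
})

test_that("the objective decreases under a short gradient-descent run", {
  set.seed(76)
  cfg <- modelConfig(channels = c(4L, 8L, 16L, 32L, 64L), depths = 1L,
                     heads = c(2L, 2L, 2L, 2L, 2L), input_size = 32L)
  m <- buildModel(cfg, seed = 1)
  samples <- smoke_samples(4, size = 32L, base_seed = 400L)
  tc <- trainConfig(lr = 1e-3, max_iters = 50L, batch_size = 2L,
                    resize = 32L, seed = 5L)
  r <- trainModel(m, tc, samples, augment = FALSE)
  expect_lt(mean(tail(r$log$loss, 5)), mean(head(r$log$loss, 5)))
})
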