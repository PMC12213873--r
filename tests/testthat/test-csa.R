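# Cross-shape strip attention and the transformer block built on it.

test_that("strip partition covers the grid with non-overlapping strips", {
  sp <- stripPartition(c(4, 6), 2, "horizontal")
  expect_equal(sp$M, 2L)
  expect_true(all(lengths(sp$strips) == 2 * 6))
  all_idx <- unlist(sp$strips)
  expect_setequal(all_idx, 1:24)              # bijection, no padding needed
  expect_equal(anyDuplicated(all_idx), 0L)
  # sw = H: single strip covering the whole grid
  sp1 <- stripPartition(c(4, 6), 4, "horizontal")
  expect_equal(sp1$M, 1L)
  expect_setequal(sp1$strips[[1]], 1:24)
  # non-divisible extent: padded entries marked 0, real entries cover grid
  sp2 <- stripPartition(c(5, 3), 3, "horizontal")
  expect_equal(sp2$M, 2L)
  expect_true(all(lengths(sp2$strips) == 9))
  real <- unlist(sp2$strips); real <- real[real > 0]
  expect_setequal(real, 1:15)
  # vertical orientation
  spv <- stripPartition(c(3, 4), 2, "vertical")
  expect_equal(spv$M, 2L)
  expect_setequal(unlist(spv$strips), 1:12)
  expect_error(stripPartition(c(4, 4), 0, "horizontal"), "sw")
  expect_error(stripPartition(c(4, 4), 5, "horizontal"), "sw")
})

test_that("strip attention matches brute-force oracles", {
  set.seed(21)
  C <- 8; dk <- 4
  Wq <- rnm(C, dk); Wk <- rnm(C, dk); Wv <- rnm(C, dk)
  # n = 1: softmax over one logit -> output is that token's value vector
  x1 <- rnm(1, C)
  expect_equal(stripAttention(x1, Wq, Wk, Wv), x1 %*% Wv, tolerance = 1e-12)
  # all keys equal -> uniform weights -> mean of values
  xeq <- rnm(6, C)
  out <- stripAttention(xeq, Wq, matrix(0, C, dk), Wv)
  V <- xeq %*% Wv
  expect_equal(out, matrix(colMeans(V), 6, dk, byrow = TRUE),
               tolerance = 1e-10)
  # attention rows sum to 1: constant value channel stays constant
  xc <- cbind(rnm(7, C - 1), 1)
  Wv1 <- matrix(0, C, dk); Wv1[C, ] <- 1
  expect_equal(stripAttention(xc, rnm(C, dk), rnm(C, dk), Wv1),
               matrix(1, 7, dk), tolerance = 1e-10)
  # restriction to a strip == full-grid attention with -Inf mask outside
  Xg <- rnm(20, C)
  keep <- rep(FALSE, 20); keep[6:11] <- TRUE
  expect_equal(stripAttention(Xg[keep, ], Wq, Wk, Wv),
               masked_attention(Xg, Wq, Wk, Wv, keep), tolerance = 1e-10)
})

test_that("csa with full-extent strips equals vanilla multi-head attention", {
  set.seed(22)
  H <- W <- 8; C <- 16; K <- 4
  p <- csaParams(C, K, sw = 8)
  X <- rnm(H, W, C)
  got <- fm2m(csa(X, p))
  want <- vanilla_mha(fm2m(X), p, K)
  expect_lt(rel_err(got, want), 1e-5)
})

test_that("strip locality: outputs depend only on their own strips", {
  set.seed(23)
  H <- W <- 6; C <- 8; K <- 4; sw <- 2
  p <- csaParams(C, K, sw)
  X <- rnm(H, W, C)
  y <- csa(X, p)
  # perturb one pixel; positions in a different row-strip AND different
  # column-strip are exactly unchanged
  X2 <- X; X2[1, 1, ] <- X2[1, 1, ] + 3
  y2 <- csa(X2, p)
  untouched_rows <- 3:6   # row strips not containing row 1
  untouched_cols <- 3:6
  expect_identical(y2[untouched_rows, untouched_cols, ],
                   y[untouched_rows, untouched_cols, ])
  expect_false(isTRUE(all.equal(y2[1, 1, ], y[1, 1, ])))
  # swapping two complete horizontal strips (Wo = identity) swaps the
  # horizontal-head output channels accordingly
  pid <- p; pid$Wo <- diag(C); pid$bo <- numeric(C)
  Xs <- X
  Xs[1:2, , ] <- X[3:4, , ]; Xs[3:4, , ] <- X[1:2, , ]
  ya <- csa(X, pid); yb <- csa(Xs, pid)
  hcols <- seq_len(C / 2)    # first K/2 heads = horizontal group
  expect_equal(yb[1:2, , hcols], ya[3:4, , hcols], tolerance = 1e-12)
  expect_equal(yb[5:6, , hcols], ya[5:6, , hcols], tolerance = 1e-12)
})

test_that("attention cost grows linearly in the strip width", {
  count_scores <- function(sw) {
    st <- ns$strip_idx(1L, 12L, 12L, as.integer(sw))
    sum(vapply(st$h, function(s) length(s)^2, 1)) +
      sum(vapply(st$v, function(s) length(s)^2, 1))
  }
  expect_equal(count_scores(2) / count_scores(1), 2)
  expect_equal(count_scores(4) / count_scores(2), 2)
  expect_equal(count_scores(6) / count_scores(3), 2)
})

test_that("cst block: double residual identity and shape preservation", {
  set.seed(24)
  X <- rnm(5, 7, 8)
  pz <- cstParams(8, 2, 3, 4, zero = TRUE)
  expect_identical(cstBlock(X, pz), X)
  p <- cstParams(8, 2, 3, 4)
  for (d in list(c(4, 4, 8), c(3, 9, 16))) {
    Xi <- rnm(d[1], d[2], d[3])
    pp <- cstParams(d[3], 2, 3, 4)
    expect_identical(dim(cstBlock(Xi, pp)), dim(Xi))
  }
  expect_error(csaParams(8, 3), "even")
  expect_error(csaParams(9, 2), "divisible")
})

test_that("gradient through the cst block matches finite differences", {
  set.seed(25)
  H <- W <- 4; C <- 8
  p <- cstParams(C, 2, 3, 2)
  p$attn$Wo <- rnm(C, C) * 0.1
  p$W2 <- rnm(2 * C, C) * 0.1
  x <- rnm(H * W, C)
  err <- gradcheck_op(function(tp, n)
    ns$`.cst_block`(tp, n[[1]],
                    list(ln1_g = n[[2]], ln1_b = n[[3]],
                         attn = list(Wq = n[[4]], Wk = n[[5]], Wv = n[[6]],
                                     Wo = n[[7]], bo = n[[8]],
                                     K = 2L, sw = 3L),
                         ln2_g = n[[9]], ln2_b = n[[10]],
                         W1 = n[[11]], b1 = n[[12]],
                         W2 = n[[13]], b2 = n[[14]]),
                    1L, H, W),
    list(x, p$ln1_g, p$ln1_b, p$attn$Wq, p$attn$Wk, p$attn$Wv,
         p$attn$Wo, p$attn$bo, p$ln2_g, p$ln2_b, p$W1, p$b1, p$W2, p$b2),
    eps = 1e-5, npick = 4)
  expect_lt(err, 1e-4)
})
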