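# Merge module: directional pooling, rank-1 attention map, gated fusion.

test_that("directional pooling computes row/column means", {
  set.seed(51)
  # constant map pools to the constant
  Xc <- array(2.5, c(4, 4, 3))
  p <- directionalPool(Xc)
  expect_equal(p$Z_h, matrix(2.5, 4, 3))
  expect_equal(p$Z_w, matrix(2.5, 4, 3))
  # single nonzero pixel: v/W in its row, v/H in its column
  H <- 4; W <- 6
  X <- array(0, c(H, W, 2)); X[2, 5, ] <- c(3, -1)
  p <- directionalPool(X)
  expect_equal(p$Z_h[2, ], c(3, -1) / W)
  expect_equal(p$Z_w[5, ], c(3, -1) / H)
  expect_equal(sum(abs(p$Z_h[-2, ])), 0)
  expect_equal(sum(abs(p$Z_w[-5, ])), 0)
  # linearity
  A <- rnm(3, 3, 2); B <- rnm(3, 3, 2)
  pa <- directionalPool(A); pb <- directionalPool(B)
  pab <- directionalPool(2 * A - 3 * B)
  expect_equal(pab$Z_h, 2 * pa$Z_h - 3 * pb$Z_h, tolerance = 1e-12)
})

test_that("every channel slice of the attention map has rank <= 1", {
  set.seed(52)
  H <- W <- 6; C <- 8
  p <- mtmParams(C)
  Zp <- directionalPool(rnm(H, W, C))
  O <- mtmAttentionMap(Zp$Z_h, Zp$Z_w, p)
  expect_equal(dim(O), c(H, W, C))
  for (c in seq_len(C)) {
    sv <- svd(O[, , c])$d
    expect_lt(sv[2], 1e-10 * max(sv[1], 1))
  }
  # identity-like branches, no bias: O is the outer product structure by
  # construction even for arbitrary weights; zero weights give O == 0
  pz <- mtmParams(C, zero = TRUE)
  Oz <- mtmAttentionMap(Zp$Z_h, Zp$Z_w, pz)
  expect_equal(Oz, array(0, c(H, W, C)))
})

test_that("gated fusion: zero map gives 1.5x, and |out - X| <= |X|", {
  set.seed(53)
  H <- W <- 4; C <- 8
  E_T <- rnm(H, W, C); E_M <- rnm(H, W, C)
  # zero branch weights (O = 0) but live input projection: out = 1.5 X
  p <- mtmParams(C, zero = TRUE)
  p$Wp <- rnm(2 * C, C)
  X <- ns$tokens_to_fm(cbind(fm2m(E_T), fm2m(E_M)) %*% p$Wp, H, W)
  out <- mtmFuse(E_T, E_M, p)
  expect_equal(out, 1.5 * X, tolerance = 1e-12)
  # general weights: sigmoid gate is bounded, so |out - X| <= |X|
  pg <- mtmParams(C)
  Xg <- ns$tokens_to_fm(cbind(fm2m(E_T), fm2m(E_M)) %*% pg$Wp +
                          rep(pg$bp, each = H * W), H, W)
  outg <- mtmFuse(E_T, E_M, pg)
  expect_true(all(abs(outg - Xg) <= abs(Xg) + 1e-12))
  expect_identical(dim(outg), dim(E_T))
  # determinism: identical inputs and weights, bit-identical outputs
  expect_identical(mtmFuse(E_T, E_M, pg), mtmFuse(E_T, E_M, pg))
  # gate disabled: plain pointwise fusion (ablation baseline)
  pn <- mtmParams(C, gate = FALSE)
  expect_equal(mtmFuse(E_T, E_M, pn),
               ns$tokens_to_fm(cbind(fm2m(E_T), fm2m(E_M)) %*% pn$Wp +
                                 rep(pn$bp, each = H * W), H, W),
               tolerance = 1e-12)
  expect_error(mtmFuse(E_T, rnm(H, W, C + 2), pg), "shape")
  expect_error(mtmParams(9), "divisible")
})

test_that("non-square maps use the length-concatenated path", {
  set.seed(54)
  H <- 6; W <- 4; C <- 8
  p <- mtmParams(C, square = FALSE)
  E_T <- rnm(H, W, C); E_M <- rnm(H, W, C)
  out <- mtmFuse(E_T, E_M, p)
  expect_identical(dim(out), c(6L, 4L, 8L))
  Zp <- directionalPool(rnm(H, W, C))
  O <- mtmAttentionMap(Zp$Z_h, Zp$Z_w, p)
  expect_equal(dim(O), c(H, W, C))
  for (c in c(1, 5)) expect_lt(svd(O[, , c])$d[2], 1e-10)
})
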