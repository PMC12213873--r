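# Pyramid assembly: auxiliary convolution, downsampling, encoder/decoder
# contracts, profiling, gradient coverage, checkpointing.

test_that("depthwise-separable conv: parameter arithmetic and identity", {
  p <- dwsParams(3, 8, k = 3)
  conv_params <- length(p$dw) + length(p$pw)
  expect_equal(conv_params, 3 * 9 + 3 * 8)       # < full conv's 3*8*9
  expect_lt(conv_params + length(p$db) + length(p$pb), 3 * 8 * 9)
  set.seed(61)
  X <- rnm(5, 6, 3)
  out <- dwsConv(X, p)
  expect_equal(dim(out), c(5, 6, 8))
  # identity taps: output = activation(norm(input))
  pid <- dwsParams(4, 4, k = 3, identity = TRUE)
  Xi <- rnm(4, 4, 4)
  got <- dwsConv(Xi, pid)
  want <- ns$tokens_to_fm(
    ns$op_gelu(NULL, ns$op_layernorm(NULL, fm2m(Xi), rep(1, 4),
                                     numeric(4))), 4, 4)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("bilinear downsampling matches hand-computed values", {
  # constant image stays constant
  Xc <- array(3, c(4, 4, 2))
  expect_equal(downsampleFeature(Xc), array(3, c(2, 2, 2)), tolerance = 1e-12)
  # linear ramp f(h) = h, half scale, align-corners-false centers:
  # out row i samples source 2i - 0.5 -> values 1.5 and 3.5
  Xr <- array(rep(1:4, 4), c(4, 4, 1))
  d <- downsampleFeature(Xr)
  expect_equal(d[, , 1], matrix(c(1.5, 1.5, 3.5, 3.5), 2, byrow = TRUE),
               tolerance = 1e-12)
  # two successive downsamples quarter the resolution; odd extents round up
  set.seed(62)
  X <- rnm(8, 8, 3)
  expect_equal(dim(downsampleFeature(downsampleFeature(X))), c(2, 2, 3))
  expect_equal(dim(downsampleFeature(rnm(5, 7, 2))), c(3, 4, 2))
  # pointwise projection applies the channel change
  W <- rnm(3, 5)
  expect_equal(dim(downsampleFeature(X, W)), c(4, 4, 5))
  expect_error(downsampleFeature(rnm(1, 4, 2)), "extent")
})

test_that("encoder produces the halving pyramid with the configured widths", {
  set.seed(63)
  cfg <- tiny_config()
  m <- buildModel(cfg, seed = 2)
  img <- rnm(64, 64, 3)
  bundles <- mtuEncode(m, img)
  expect_length(bundles, 5L)
  sizes <- c(32, 16, 8, 4, 2)
  for (i in 1:5) {
    for (nm in c("E_T", "E_M", "E_D", "fused")) {
      d <- dim(bundles[[i]][[nm]])
      expect_equal(d, c(sizes[i], sizes[i], cfg@channels[i]))
      expect_true(all(is.finite(bundles[[i]][[nm]])))
    }
  }
  expect_error(mtuEncode(m, rnm(60, 60, 3)), "divisible")
})

test_that("with zero block weights each encoder branch is the identity", {
  set.seed(64)
  cfg <- tiny_config()
  params <- ns$build_params(cfg, zero_blocks = TRUE)
  img <- rnm(64, 64, 3)
  enc <- ns$`.encode`(NULL, params, cfg, fm2m(img), 1L, 64L, 64L)
  # expected: per stage, the branch's own downsampled+projected input
  xt <- xm <- fm2m(img)
  hc <- 64L
  for (i in 1:5) {
    hn <- hc %/% 2L
    S <- ns$resize_op(hc, hc, hn, hn)
    st <- params$stages[[i]]
    xt <- as.matrix(S %*% xt) %*% st$down_t$W +
      rep(st$down_t$b, each = hn * hn)
    xm <- as.matrix(S %*% xm) %*% st$down_m$W +
      rep(st$down_m$b, each = hn * hn)
    expect_equal(enc$bundles[[i]]$E_T, xt, tolerance = 1e-12)
    expect_equal(enc$bundles[[i]]$E_M, xm, tolerance = 1e-12)
    hc <- hn
  }
})

test_that("decoder returns full-resolution finite logits", {
  set.seed(65)
  cfg <- tiny_config()
  for (s in 1:2) {
    m <- buildModel(cfg, seed = s)
    img <- rnm(64, 64, 3)
    logits <- mtuForward(m, img)
    expect_equal(dim(logits), c(64, 64, 1))
    expect_true(all(is.finite(logits)))
  }
  # decode() on encode() output reproduces the full forward pass
  m <- buildModel(cfg, seed = 9)
  img <- rnm(64, 64, 3)
  expect_equal(mtuDecode(m, mtuEncode(m, img), c(64, 64)),
               mtuForward(m, img), tolerance = 1e-12)
})

test_that("deterministic: same seed, same parameters, same logits", {
  cfg <- tiny_config()
  m1 <- buildModel(cfg, seed = 7)
  m2 <- buildModel(cfg, seed = 7)
  expect_identical(m1@params, m2@params)
  img <- array(0.3, c(64, 64, 3))
  expect_identical(mtuForward(m1, img), mtuForward(m2, img))
})

test_that("a scalar loss sends gradient into every parameter group", {
  set.seed(66)
  cfg <- modelConfig(channels = c(4L, 8L, 16L, 32L, 64L), depths = 1L,
                     heads = c(2L, 2L, 2L, 2L, 2L), input_size = 32L)
  m <- buildModel(cfg, seed = 1)
  img <- rnm(32, 32, 3)
  mask <- (rnm(32, 32) > 0) * 1
  tp <- ns$new_tape()
  pn <- ns$wrap_params(m@params)
  out <- ns$`.forward`(tp, pn, cfg, fm2m(img), 1L, 32L, 32L)
  loss <- ns$op_seg_loss(tp, out, as.numeric(t(mask)))
  ns$backward(tp, loss)
  g <- ns$grad_of(pn)
  gnorm <- function(x) sum(unlist(ns$flatten_params(x))^2)
  for (i in 1:5) {
    st <- g$stages[[i]]
    expect_gt(gnorm(st$cst), 0)
    expect_gt(gnorm(st$vme), 0)
    expect_gt(gnorm(st$dws), 0)
    expect_gt(gnorm(st$mtm), 0)
    expect_gt(gnorm(g$dec[[i]]), 0)
  }
  expect_gt(gnorm(g$head), 0)
})

test_that("profile parameter count equals the instantiated model's", {
  cfgs <- list(tiny_config(),
               modelConfig(channels = c(4L, 8L, 16L, 32L, 64L),
                           depths = c(1L, 2L, 1L, 2L, 1L),
                           heads = c(2L, 2L, 2L, 2L, 2L),
                           input_size = 32L))
  for (cfg in cfgs) {
    pr <- profileModel(cfg)
    m <- buildModel(cfg, seed = 1)
    expect_identical(pr$params, paramCount(m))
  }
  # FLOPs are reported under both conventions, factor 2 apart
  pr <- profileModel(tiny_config())
  expect_equal(pr$flops, 2 * pr$macs)
  # convolutional compute scales ~4x when the input side doubles
  r <- profileModel(tiny_config(128L))$macs / profileModel(tiny_config(64L))$macs
  expect_gt(r, 3.5); expect_lt(r, 4.3)
})

test_that("checkpoints round-trip the model exactly", {
  cfg <- tiny_config()
  m <- buildModel(cfg, seed = 3)
  m@iter <- 17L
  f <- tempfile(fileext = ".rds")
  saveCheckpoint(m, f)
  m2 <- loadCheckpoint(f)
  expect_identical(m2@params, m@params)
  expect_identical(m2@iter, 17L)
  expect_identical(m2@config@depths, cfg@depths)
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(format = "other"), bad)
  expect_error(loadCheckpoint(bad), "format")
  unlink(c(f, bad))
})
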