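# ---------------------------------------------------------------------------
# Five-stage dual-encoder pyramid: per stage, each branch (cross-shape
# transformer, Vision-Mamba, depthwise-separable auxiliary) consumes its
# own previous-stage output bilinearly downsampled to half resolution;
# the CST and VME outputs are fused by the merge module, and the decoder
# consumes (fused, upsampled previous decoder, auxiliary) triples.
# ---------------------------------------------------------------------------

stage_sizes <- function(H, W) {
  out <- matrix(0L, 5L, 2L)
  for (i in 1:5) {
    H <- as.integer(ceiling(H / 2)); W <- as.integer(ceiling(W / 2))
    out[i, ] <- c(H, W)
  }
  out
}

#' Construct depthwise-separable convolution parameters
#'
#' @param Cin,Cout input/output channel counts.
#' @param k spatial kernel size.
#' @param zero zero-initialize weights.
#' @param identity initialize the depthwise tap to the identity (center
#'   tap 1) and the pointwise map to the identity (requires `Cin == Cout`).
#' @return parameter list (depthwise taps, pointwise projection, norm).
#' @export
dwsParams <- function(Cin, Cout, k = 3L, zero = FALSE, identity = FALSE) {
  kk <- k * k
  if (identity) {
    dw <- matrix(0, kk, Cin); dw[(kk + 1L) %/% 2L, ] <- 1
    pw <- diag(Cin)
  } else if (zero) {
    dw <- matrix(0, kk, Cin); pw <- matrix(0, Cin, Cout)
  } else {
    dw <- matrix(stats::rnorm(kk * Cin, sd = sqrt(2 / kk)), kk, Cin)
    pw <- rnorm_mat(Cin, Cout, sqrt(2 / Cin))
  }
  list(dw = dw, db = numeric(Cin), pw = pw, pb = numeric(Cout),
       ln_g = rep(1, Cout), ln_b = numeric(Cout), k = as.integer(k))
}

.dws_conv <- function(tp, x, p, B, H, W) {
  k <- .val_int(p$k)
  y <- op_dwconv(tp, x, p$dw, p$db, conv_idx(B, H, W, k))
  y <- op_linear(tp, y, p$pw, p$pb)
  op_gelu(tp, op_layernorm(tp, y, p$ln_g, p$ln_b))
}

#' Depthwise-separable convolution layer
#'
#' A per-channel `k x k` depthwise convolution (same padding) followed by
#' a pointwise 1x1 convolution, layer normalization and GELU. Parameter
#' count is `Cin*k^2 + Cin*Cout` (plus biases and norm), far below a full
#' convolution's `Cin*Cout*k^2`.
#'
#' @param X `H x W x Cin` feature array.
#' @param params parameters from [dwsParams()].
#' @return `H x W x Cout` array.
#' @export
dwsConv <- function(X, params) {
  d <- dim(X)
  out <- .dws_conv(NULL, fm_to_tokens(X), params, 1L, d[1], d[2])
  tokens_to_fm(out, d[1], d[2])
}

#' Bilinear half-resolution downsampling
#'
#' Bilinearly interpolates the map to `(ceiling(H/2), ceiling(W/2))`; an
#' optional pointwise projection applies the next stage's channel change.
#'
#' @param X `H x W x C` feature array with `H, W >= 2`.
#' @param W_proj optional `C x C_out` pointwise projection.
#' @param b_proj optional bias.
#' @return downsampled array.
#' @export
downsampleFeature <- function(X, W_proj = NULL, b_proj = NULL) {
  d <- dim(X)
  if (d[1] < 2 || d[2] < 2)
    stop("downsampleFeature: extent must be at least 2 pixels")
  Ho <- as.integer(ceiling(d[1] / 2)); Wo <- as.integer(ceiling(d[2] / 2))
  out <- op_spmm(NULL, resize_op(d[1], d[2], Ho, Wo), fm_to_tokens(X))
  if (!is.null(W_proj)) {
    out <- out %*% W_proj
    if (!is.null(b_proj)) out <- out + rep(b_proj, each = nrow(out))
  }
  tokens_to_fm(out, Ho, Wo)
}

# --------------------------- parameter assembly ----------------------------

proj_params <- function(Cin, Cout, zero = FALSE) {
  list(W = if (zero) matrix(0, Cin, Cout) else
    rnorm_mat(Cin, Cout, sqrt(2 / Cin)), b = numeric(Cout))
}

build_params <- function(cfg, zero_blocks = FALSE) {
  ch <- cfg@channels; hs <- cfg@heads; dp <- cfg@depths; sw <- cfg@sw
  sz <- stage_sizes(cfg@input_size, cfg@input_size)
  stages <- vector("list", 5L)
  cprev <- 3L
  for (i in 1:5) {
    C <- ch[i]
    stages[[i]] <- list(
      down_t = proj_params(cprev, C),
      down_m = proj_params(cprev, C),
      down_d = proj_params(cprev, C),
      cst = lapply(seq_len(dp[i]), function(j)
        cstParams(C, hs[i], sw[i], cfg@mlp_ratio, zero = zero_blocks)),
      vme = vmeStageParams(C, sz[i, 1] * sz[i, 2], dp[i], cfg@d_state,
                           cfg@expand, cfg@ssm_kernel, zero = zero_blocks),
      dws = dwsParams(C, C, cfg@dws_kernel),
      mtm = mtmParams(C, square = TRUE)
    )
    cprev <- C
  }
  dec <- vector("list", 5L)
  for (i in 5:1) {
    C <- ch[i]
    cin <- if (i == 5L) 2L * C else 3L * C
    dec[[i]] <- list(
      conv1 = list(W = rnorm_mat(9L * cin, C, sqrt(2 / (9 * cin))),
                   b = numeric(C)),
      ln1_g = rep(1, C), ln1_b = numeric(C),
      conv2 = list(W = rnorm_mat(9L * C, C, sqrt(2 / (9 * C))),
                   b = numeric(C)),
      ln2_g = rep(1, C), ln2_b = numeric(C))
    if (i < 5L) dec[[i]]$up <- proj_params(ch[i + 1L], C)
  }
  head <- proj_params(ch[1], cfg@out_channels)
  list(stages = stages, dec = dec, head = head)
}

#' Build a model with freshly initialized parameters
#'
#' Residual branch output projections are zero-initialized so every block
#' starts as the identity; other weights use scaled Gaussian
#' initialization. Fully deterministic given `seed`.
#'
#' @param config a [ModelConfig-class].
#' @param seed RNG seed for initialization.
#' @return an [MTUNet-class] model object.
#' @export
buildModel <- function(config = modelConfig(), seed = 1L) {
  params <- with_seed(seed, build_params(config))
  new("MTUNet", config = config, params = params,
      seed = as.integer(seed), iter = 0L)
}

# ------------------------------ forward cores ------------------------------

# encoder over token matrices; returns per-stage bundles and sizes
.encode <- function(tp, p, cfg, x, B, H, W) {
  sz <- stage_sizes(H, W)
  xt <- xm <- xd <- x
  hc <- H; wc <- W
  bundles <- vector("list", 5L)
  for (i in 1:5) {
    hn <- sz[i, 1]; wn <- sz[i, 2]
    S <- resize_op(hc, wc, hn, wn, B)
    st <- p$stages[[i]]
    xt <- op_linear(tp, op_spmm(tp, S, xt), st$down_t$W, st$down_t$b)
    xm <- op_linear(tp, op_spmm(tp, S, xm), st$down_m$W, st$down_m$b)
    xd <- op_linear(tp, op_spmm(tp, S, xd), st$down_d$W, st$down_d$b)
    for (blk in st$cst) xt <- .cst_block(tp, xt, blk, B, hn, wn)
    xm <- .vme_stage(tp, xm, st$vme, B, hn, wn)
    xd <- .dws_conv(tp, xd, st$dws, B, hn, wn)
    fused <- .mtm(tp, xt, xm, st$mtm, B, hn, wn)
    bundles[[i]] <- list(E_T = xt, E_M = xm, E_D = xd, fused = fused)
    hc <- hn; wc <- wn
  }
  list(bundles = bundles, sizes = sz)
}

# decoder: deepest to shallowest, then 1x1 head at full resolution
.decode <- function(tp, p, cfg, bundles, sizes, B, H, W) {
  d <- NULL
  for (i in 5:1) {
    hn <- sizes[i, 1]; wn <- sizes[i, 2]
    de <- p$dec[[i]]
    parts <- list(bundles[[i]]$fused)
    if (!is.null(d)) {
      S <- resize_op(sizes[i + 1L, 1], sizes[i + 1L, 2], hn, wn, B)
      parts <- c(parts, list(op_linear(tp, op_spmm(tp, S, d),
                                       de$up$W, de$up$b)))
    }
    parts <- c(parts, list(bundles[[i]]$E_D))
    x <- op_concat_cols(tp, parts)
    ci <- conv_idx(B, hn, wn, 3L)
    x <- op_gelu(tp, op_layernorm(tp, op_conv2d(tp, x, de$conv1$W,
                                                de$conv1$b, ci),
                                  de$ln1_g, de$ln1_b))
    d <- op_gelu(tp, op_layernorm(tp, op_conv2d(tp, x, de$conv2$W,
                                                de$conv2$b, ci),
                                  de$ln2_g, de$ln2_b))
  }
  Sfull <- resize_op(sizes[1, 1], sizes[1, 2], H, W, B)
  op_linear(tp, op_spmm(tp, Sfull, d), p$head$W, p$head$b)
}

.forward <- function(tp, p, cfg, x, B, H, W) {
  enc <- .encode(tp, p, cfg, x, B, H, W)
  .decode(tp, p, cfg, enc$bundles, enc$sizes, B, H, W)
}

# ------------------------------- public API --------------------------------

#' Run the dual encoder over an image
#'
#' @param model an [MTUNet-class] model.
#' @param image `H x W x 3` array (H, W divisible by 32).
#' @return list of 5 stage bundles, each with `E_T`, `E_M`, `E_D` and
#'   `fused` feature arrays at stage resolution `input / 2^i`.
#' @export
mtuEncode <- function(model, image) {
  d <- dim(image)
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L)
    stop("mtuEncode: image extents must be divisible by 32")
  enc <- .encode(NULL, model@params, model@config, fm_to_tokens(image),
                 1L, d[1], d[2])
  lapply(seq_len(5L), function(i) {
    b <- enc$bundles[[i]]
    lapply(b, tokens_to_fm, H = enc$sizes[i, 1], W = enc$sizes[i, 2])
  })
}

#' Decode encoder bundles into segmentation logits
#'
#' @param model an [MTUNet-class] model.
#' @param bundles output of [mtuEncode()].
#' @param size integer `c(H, W)` of the original image.
#' @return `H x W x out_channels` logit array.
#' @export
mtuDecode <- function(model, bundles, size) {
  sizes <- stage_sizes(size[1], size[2])
  tb <- lapply(bundles, function(b) lapply(b, fm_to_tokens))
  out <- .decode(NULL, model@params, model@config, tb, sizes, 1L,
                 size[1], size[2])
  tokens_to_fm(out, size[1], size[2])
}

#' Full forward pass to segmentation logits
#'
#' @param model an [MTUNet-class] model.
#' @param image `H x W x 3` array (extents divisible by 32).
#' @return `H x W x out_channels` logit array (apply `plogis` for
#'   probabilities).
#' @export
mtuForward <- function(model, image) {
  d <- dim(image)
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L)
    stop("mtuForward: image extents must be divisible by 32")
  out <- .forward(NULL, model@params, model@config, fm_to_tokens(image),
                  1L, d[1], d[2])
  tokens_to_fm(out, d[1], d[2])
}

# ------------------------------ checkpointing ------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint is a self-describing list (format tag, configuration
#' fields, parameter arrays, seed, iteration count) serialized with
#' `saveRDS`.
#'
#' @param model an [MTUNet-class] model.
#' @param path file path.
#' @return `loadCheckpoint` returns the restored [MTUNet-class] model.
#' @export
saveCheckpoint <- function(model, path) {
  cfg <- model@config
  obj <- list(format = "mtunet-checkpoint-v1",
              config = list(channels = cfg@channels, depths = cfg@depths,
                            heads = cfg@heads, sw = cfg@sw,
                            mlp_ratio = cfg@mlp_ratio,
                            d_state = cfg@d_state, expand = cfg@expand,
                            ssm_kernel = cfg@ssm_kernel,
                            dws_kernel = cfg@dws_kernel,
                            input_size = cfg@input_size,
                            out_channels = cfg@out_channels),
              params = model@params, seed = model@seed, iter = model@iter)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "mtunet-checkpoint-v1"))
    stop("loadCheckpoint: unrecognized checkpoint format")
  cfg <- do.call(modelConfig, obj$config)
  new("MTUNet", config = cfg, params = obj$params,
      seed = as.integer(obj$seed), iter = as.integer(obj$iter))
}
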