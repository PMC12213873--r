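# ---------------------------------------------------------------------------
# Architecture budget profiling: exact trainable-parameter count and
# multiply-accumulate (MAC) count of one forward pass, both derived in
# closed form from the configuration (the parameter count is additionally
# checked against instantiated models in the test suite).
#
# MAC convention: every multiply-accumulate of the dense numerical work is
# counted -- projections/convolutions, attention score and value products,
# the SSM recurrence (5 MACs per channel-state-step plus skip), bilinear
# interpolation (4 taps per output), gating and attention-map multiplies.
# Normalizations, softmax and activation functions are excluded. FLOPs are
# reported both as 1 MAC = 1 FLOP (`gmacs`) and 1 MAC = 2 FLOPs (`gflops`,
# the reported convention).
# ---------------------------------------------------------------------------

strip_lengths <- function(extent, other, sw) {
  M <- ceiling(extent / sw)
  widths <- rep(sw, M)
  if (extent %% sw != 0L) widths[M] <- extent %% sw
  widths * other
}

count_cst <- function(C, K, r) {
  h <- round(r * C)
  2 * C + (4 * C^2 + C) + 2 * C + C * h + h + h * C + C
}

count_vim <- function(d, ds, e, k) {
  di <- e * d
  per_dir <- k * di + di + di^2 + di + 2 * (di * ds + ds) +
    di * ds + di
  2 * d + d * 2 * di + 2 * di + 2 * per_dir + di * d + d
}

#' Profile a model configuration
#'
#' Computes the exact trainable-parameter count and the forward-pass
#' multiply-accumulate count at the given input size, in closed form from
#' the configuration. Multiplies of projections, convolutions, attention
#' scores/values, the SSM recurrence, bilinear interpolation and gating
#' are counted; normalizations, softmax and activations are not. FLOPs
#' are reported under both conventions (1 or 2 FLOPs per MAC); the
#' headline `gflops` figure uses 2 FLOPs per MAC.
#'
#' @param config a [ModelConfig-class].
#' @param input_size square input resolution (defaults to the config's).
#' @return list with `params`, `params_M`, `macs`, `gmacs`, `flops`,
#'   `gflops`, and a per-component parameter breakdown.
#' @export
profileModel <- function(config = modelConfig(),
                         input_size = config@input_size) {
  ch <- config@channels; dp <- config@depths; hs <- config@heads
  sw <- config@sw; r <- config@mlp_ratio
  ds <- config@d_state; e <- config@expand; kssm <- config@ssm_kernel
  kdws <- config@dws_kernel
  sz <- stage_sizes(input_size, input_size)
  params <- 0; macs <- 0
  breakdown <- numeric(0)
  cprev <- 3L
  hc <- wc <- input_size
  for (i in 1:5) {
    C <- ch[i]; K <- hs[i]; d <- dp[i]
    H <- sz[i, 1]; W <- sz[i, 2]; N <- H * W
    di <- e * C
    # three branch downsamples (bilinear + pointwise projection)
    p_stage <- 3 * (cprev * C + C)
    m_stage <- 3 * (N * cprev * 4 + N * cprev * C)
    # CST branch
    p_stage <- p_stage + d * count_cst(C, K, r)
    dk <- C %/% K
    sc_h <- sum(strip_lengths(H, W, sw[i])^2) * dk * 2 * (K / 2)
    sc_v <- sum(strip_lengths(W, H, sw[i])^2) * dk * 2 * (K / 2)
    hmlp <- round(r * C)
    m_stage <- m_stage + d * (4 * N * C^2 + sc_h + sc_v + 2 * N * C * hmlp)
    # VME branch
    p_stage <- p_stage + C^2 + C + N * C + d * count_vim(C, ds, e, kssm)
    m_vim <- N * C * 2 * di +
      2 * (N * kssm * di + N * di^2 + 2 * N * di * ds +
             N * di * ds * 5 + N * di + N * di) +
      N * di * C
    m_stage <- m_stage + N * C^2 + d * m_vim
    # auxiliary depthwise-separable branch
    p_stage <- p_stage + kdws^2 * C + C + C^2 + C + 2 * C
    m_stage <- m_stage + N * kdws^2 * C + N * C^2
    # merge module
    p_stage <- p_stage + 2 * C * C + C + 4 * (2 * C * (C / 2) + C / 2)
    m_stage <- m_stage + N * 2 * C * C + 2 * N * C +
      4 * H * 2 * C * (C / 2) + N * C + N * C
    params <- params + p_stage; macs <- macs + m_stage
    breakdown[sprintf("stage%d", i)] <- p_stage
    cprev <- C; hc <- H; wc <- W
  }
  # decoder
  p_dec <- 0; m_dec <- 0
  for (i in 5:1) {
    C <- ch[i]; H <- sz[i, 1]; W <- sz[i, 2]; N <- H * W
    cin <- if (i == 5L) 2L * C else 3L * C
    p_dec <- p_dec + 9 * cin * C + C + 2 * C + 9 * C^2 + C + 2 * C
    m_dec <- m_dec + N * 9 * cin * C + N * 9 * C^2
    if (i < 5L) {
      p_dec <- p_dec + ch[i + 1L] * C + C
      m_dec <- m_dec + N * ch[i + 1L] * 4 + N * ch[i + 1L] * C
    }
  }
  # full-resolution head
  N0 <- input_size * input_size
  p_dec <- p_dec + ch[1] * config@out_channels + config@out_channels
  m_dec <- m_dec + N0 * ch[1] * 4 + N0 * ch[1] * config@out_channels
  params <- params + p_dec; macs <- macs + m_dec
  breakdown["decoder"] <- p_dec
  list(params = params, params_M = params / 1e6,
       macs = macs, gmacs = macs / 1e9,
       flops = 2 * macs, gflops = 2 * macs / 1e9,
       breakdown = breakdown)
}

#' Print a profiling report
#'
#' @param config a [ModelConfig-class].
#' @param input_size square input resolution.
#' @return invisibly, the [profileModel()] list.
#' @export
profileReport <- function(config = modelConfig(),
                          input_size = config@input_size) {
  pr <- profileModel(config, input_size)
  cat(sprintf("Input %d x %d\n", input_size, input_size))
  cat(sprintf("Parameters: %.1f M (%d)\n", pr$params_M, pr$params))
  cat(sprintf("Forward MACs: %.1f G;  FLOPs (2/MAC): %.1f G\n",
              pr$gmacs, pr$gflops))
  for (nm in names(pr$breakdown))
    cat(sprintf("  %-8s %10.2f M params\n", nm, pr$breakdown[nm] / 1e6))
  invisible(pr)
}
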