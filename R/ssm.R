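# ---------------------------------------------------------------------------
# Selective state-space core: softplus step-size transform, zero-order-hold
# discretization, the sequential selective scan, and the bidirectional
# gated (Vim-style) block built on top of it.
# ---------------------------------------------------------------------------

#' Positivity transform for the state-space step size
#'
#' Applies the softplus map `log(1 + exp(x))` used to keep the
#' input-dependent discretization step \eqn{\Delta} strictly positive.
#' Computed in a numerically stable form; smooth and monotone.
#'
#' @param x numeric vector, matrix or array of raw (pre-activation) step
#'   sizes. Must be finite.
#' @return object of the same shape with all entries `> 0`.
#' @examples
#' positivityTransform(0)        # log(2)
#' positivityTransform(c(-1000, 1000))
#' @export
positivityTransform <- function(x) {
  if (!all(is.finite(x))) stop("positivityTransform: input must be finite")
  # clamp to the smallest positive double so the output stays > 0 even
  # where exp(-|x|) underflows
  pmax(pmax(x, 0) + log1p(exp(-abs(x))), .Machine$double.xmin)
}

#' Zero-order-hold discretization of selective SSM dynamics
#'
#' Converts continuous dynamics `(A, B)` to per-step form using the step
#' size `delta`: `A_bar = exp(delta * A)` (exact zero-order hold on the
#' diagonal evolution matrix) and `B_bar = delta * B` (simplified Euler
#' rule), the standard convention for selective state-space models.
#'
#' @param delta positive step sizes, `L x d` matrix (per step, per inner
#'   channel) or scalar.
#' @param A diagonal evolution coefficients, `d x n` matrix (negative for
#'   stable dynamics) or scalar.
#' @param B input coefficients, `L x n` matrix (per step, per state) or
#'   scalar.
#' @return list with `A_bar` (`L x d x n`, each entry in (0, 1] when
#'   `A <= 0`) and `B_bar` (`L x d x n`).
#' @examples
#' discretizeSSM(0.5, -2, 1)$A_bar  # exp(-1)
#' @export
discretizeSSM <- function(delta, A, B) {
  if (any(delta <= 0)) stop("discretizeSSM: delta must be > 0")
  delta <- as.matrix(delta)
  A <- as.matrix(A)
  B <- as.matrix(B)
  L <- nrow(delta); d <- ncol(delta); n <- ncol(A)
  if (nrow(A) != d) stop("discretizeSSM: A rows must match delta columns")
  if (nrow(B) != L && nrow(B) != 1L)
    stop("discretizeSSM: B rows must match delta rows")
  dA <- outer(delta, rep(1, n)) *
    aperm(array(A, c(d, n, L)), c(3, 1, 2))
  Bx <- if (nrow(B) == 1L) matrix(B, L, n, byrow = TRUE) else B
  Bb <- array(delta, c(L, d, n)) *
    aperm(array(t(Bx), c(n, L, d)), c(2, 3, 1))
  list(A_bar = exp(dA), B_bar = Bb)
}

#' Selective state-space scan
#'
#' Runs the linear recurrence
#' \deqn{h_t = e^{\Delta_t A} h_{t-1} + \Delta_t B_t x_t, \qquad
#'       y_t = C_t h_t + D x_t}
#' with `h_0 = 0`, sequentially over the sequence. `B`, `C` and `delta`
#' are per-step ("selective") quantities already computed from the input;
#' `A` is the learned diagonal evolution matrix and `D` a per-channel skip
#' coefficient. The scan is causal: `y_t` depends only on `x_1..x_t`.
#'
#' @param x `L x d` input sequence (d inner channels).
#' @param delta `L x d` positive step sizes.
#' @param B,C `L x n` per-step state coefficients (n states).
#' @param A `d x n` diagonal dynamics (negative entries for stability).
#' @param D length-`d` skip coefficients.
#' @return `L x d` output sequence.
#' @export
selectiveScan <- function(x, delta, B, C, A, D) {
  x <- as.matrix(x); delta <- as.matrix(delta)
  B <- as.matrix(B); C <- as.matrix(C); A <- as.matrix(A)
  L <- nrow(x); d <- ncol(x); n <- ncol(A)
  if (any(delta <= 0)) stop("selectiveScan: delta must be > 0")
  if (!all(dim(delta) == c(L, d)) || nrow(A) != d ||
      !all(dim(B) == c(L, n)) || !all(dim(C) == c(L, n)) ||
      length(D) != d)
    stop("selectiveScan: dimension mismatch between sequence and parameters")
  scan_forward_cpp(x, delta, B, C, A, as.numeric(D), as.integer(L), FALSE)$y
}

# -------------------------- parameter construction -------------------------

rnorm_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

# per-direction selective-SSM parameters
init_ssm_dir <- function(d_inner, d_state, k, zero = FALSE) {
  sdw <- if (zero) 0 else 0.02
  list(
    convw = if (zero) matrix(0, k, d_inner) else
      matrix(stats::rnorm(k * d_inner, sd = sqrt(1 / k)), k, d_inner),
    convb = numeric(d_inner),
    W_delta = rnorm_mat(d_inner, d_inner, sdw),
    b_delta = rep(log(expm1(0.05)), d_inner),  # softplus^-1(0.05)
    W_B = rnorm_mat(d_inner, d_state, sdw),
    b_B = numeric(d_state),
    W_C = rnorm_mat(d_inner, d_state, sdw),
    b_C = numeric(d_state),
    A_log = matrix(log(seq_len(d_state)), d_inner, d_state, byrow = TRUE),
    Dskip = rep(1, d_inner)
  )
}

#' Construct parameters for a bidirectional Vim block
#'
#' Builds the full parameter set of one gated bidirectional selective-SSM
#' block: layer norm, input/gate projection, two independent per-direction
#' parameter sets (causal depthwise conv, `B`/`C`/`Delta` projections,
#' `A_log`, skip `D`), and the output projection. `A` is stored as
#' `A_log` with `A = -exp(A_log)` so the continuous dynamics stay stable;
#' it is initialized to `-(1..d_state)` per channel.
#'
#' @param d_model token width of the block.
#' @param d_state number of SSM states per channel (default 16).
#' @param expand inner-width expansion factor (default 2).
#' @param k causal depthwise convolution kernel width (default 4).
#' @param zero if `TRUE`, all learned weights are zero (the block is then
#'   the identity, through its residual connection).
#' @return nested list of parameter arrays (class `vim_params`).
#' @export
vimParams <- function(d_model, d_state = 16L, expand = 2L, k = 4L,
                      zero = FALSE) {
  d_inner <- expand * d_model
  sdw <- if (zero) 0 else 0.02
  p <- list(
    ln_g = rep(1, d_model), ln_b = numeric(d_model),
    W_in = rnorm_mat(d_model, 2L * d_inner, sdw),
    b_in = numeric(2L * d_inner),
    fwd = init_ssm_dir(d_inner, d_state, k, zero),
    bwd = init_ssm_dir(d_inner, d_state, k, zero),
    W_out = matrix(0, d_inner, d_model),   # zero-init: residual identity
    b_out = numeric(d_model)
  )
  attr(p, "dims") <- list(d_model = d_model, d_state = d_state,
                          expand = expand, k = k, d_inner = d_inner)
  class(p) <- c("vim_params", "list")
  p
}

# ------------------------------ forward cores ------------------------------

# one direction: causal conv -> SiLU -> (B, C, delta) -> scan
.ssm_direction <- function(tp, xpath, pd, seqlens, reverse = FALSE) {
  k <- nrow(.val(pd$convw))
  rev_i <- if (reverse) reverse_idx(seqlens) else NULL
  xd <- if (reverse) op_rowgather(tp, xpath, rev_i) else xpath
  x1 <- op_silu(tp, op_dwconv(tp, xd, pd$convw, pd$convb,
                              causal_idx(seqlens, k)))
  delta <- op_softplus(tp, op_linear(tp, x1, pd$W_delta, pd$b_delta))
  Bm <- op_linear(tp, x1, pd$W_B, pd$b_B)
  Cm <- op_linear(tp, x1, pd$W_C, pd$b_C)
  y <- op_scan(tp, x1, delta, Bm, Cm, pd$A_log, pd$Dskip, seqlens)
  if (reverse) y <- op_rowgather(tp, y, rev_i)
  y
}

# full bidirectional gated block with residual (token matrix in/out)
.vim_block <- function(tp, x, p, seqlens) {
  d_inner <- nrow(.val(p$fwd$W_delta))
  xn <- op_layernorm(tp, x, p$ln_g, p$ln_b)
  xz <- op_linear(tp, xn, p$W_in, p$b_in)
  xpath <- op_colselect(tp, xz, seq_len(d_inner))
  zpath <- op_colselect(tp, xz, d_inner + seq_len(d_inner))
  gate <- op_silu(tp, zpath)
  yf <- op_mul(tp, .ssm_direction(tp, xpath, p$fwd, seqlens, FALSE), gate)
  yb <- op_mul(tp, .ssm_direction(tp, xpath, p$bwd, seqlens, TRUE), gate)
  ys <- op_add(tp, yf, yb)
  op_add(tp, x, op_linear(tp, ys, p$W_out, p$b_out))
}

#' Apply a bidirectional Vim block to a token sequence
#'
#' Pipeline: layer norm, linear projection into an x-path and a gating
#' z-path, then per direction (forward, and order-reversed backward, each
#' with its own parameters) a causal depthwise 1-d convolution, SiLU,
#' input-dependent `B`/`C`/`Delta`, and the selective scan. Each
#' direction's output is gated by the SiLU-activated z-path; directions
#' are summed, projected back to `d_model`, and added residually to the
#' input.
#'
#' @param tokens `L x d_model` token matrix.
#' @param params parameters from [vimParams()].
#' @return `L x d_model` output token matrix.
#' @export
vimBlock <- function(tokens, params) {
  tokens <- as.matrix(tokens)
  d <- attr(params, "dims")$d_model
  if (ncol(tokens) != d)
    stop("vimBlock: token width does not match d_model")
  .vim_block(NULL, tokens, params, nrow(tokens))
}
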