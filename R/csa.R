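# ---------------------------------------------------------------------------
# Cross-shape self-attention: non-overlapping horizontal / vertical strips,
# half the heads on each orientation, and the pre-norm transformer block
# built from it.
# ---------------------------------------------------------------------------

#' Partition a token grid into non-overlapping strips
#'
#' Divides an `H x W` grid into contiguous horizontal (or vertical) strips
#' of width `sw` tokens. When the extent is not divisible by `sw` the grid
#' is conceptually zero-padded to the next multiple: each strip has exactly
#' `sw * W` (or `H * sw`) entries, with `0` marking padded positions
#' (masked out of any attention computed on the strip).
#'
#' @param shape integer vector `c(H, W)`.
#' @param sw strip width in tokens.
#' @param orientation `"horizontal"` or `"vertical"`.
#' @return object of class `StripPartition`: list with `orientation`, `sw`,
#'   `M` (number of strips) and `strips`, a list of length-`sw*W` (or
#'   `H*sw`) integer vectors of row-major token indices (0 = padding).
#' @export
stripPartition <- function(shape, sw, orientation = c("horizontal", "vertical")) {
  orientation <- match.arg(orientation)
  H <- shape[1]; W <- shape[2]
  extent <- if (orientation == "horizontal") H else W
  if (sw < 1 || sw > extent)
    stop("stripPartition: sw must be in [1, extent]")
  M <- ceiling(extent / sw)
  strips <- vector("list", M)
  for (s in seq_len(M)) {
    lines <- (s - 1L) * sw + seq_len(sw)
    if (orientation == "horizontal") {
      idx <- outer(lines, seq_len(W), function(h, w)
        ifelse(h <= H, (h - 1L) * W + w, 0L))
      strips[[s]] <- as.integer(t(idx))
    } else {
      idx <- outer(seq_len(H), lines, function(h, w)
        ifelse(w <= W, (h - 1L) * W + w, 0L))
      strips[[s]] <- as.integer(t(idx))
    }
  }
  structure(list(orientation = orientation, sw = sw, M = M, strips = strips),
            class = "StripPartition")
}

#' Scaled dot-product attention within one strip
#'
#' Computes `softmax(Q K' / sqrt(d_k)) V` over the tokens of a single
#' strip, with `Q = X Wq`, `K = X Wk`, `V = X Wv` all taken from the same
#' strip.
#'
#' @param strip_tokens `n x C` token matrix of one strip.
#' @param Wq,Wk,Wv `C x d_k` projection matrices of one head.
#' @return `n x d_k` attended output.
#' @export
stripAttention <- function(strip_tokens, Wq, Wk, Wv) {
  X <- as.matrix(strip_tokens)
  Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
  dk <- ncol(Q)
  sc <- tcrossprod(Q, K) / sqrt(dk)
  sc <- sc - apply(sc, 1, max)
  ex <- exp(sc)
  (ex / rowSums(ex)) %*% V
}

#' Construct cross-shape attention parameters
#'
#' @param C channel width (must be divisible by `K`).
#' @param K head count (must be even: half horizontal, half vertical).
#' @param sw strip width (default 3).
#' @param zero zero-initialize all weights (identity through the residual
#'   of the enclosing block).
#' @return list of projection matrices `Wq`, `Wk`, `Wv`, `Wo` (`C x C`),
#'   bias `bo`, and the head/strip configuration.
#' @export
csaParams <- function(C, K, sw = 3L, zero = FALSE) {
  if (K %% 2L != 0L) stop("csaParams: head count K must be even")
  if (C %% K != 0L) stop("csaParams: C must be divisible by K")
  sdw <- if (zero) 0 else 0.02
  list(Wq = rnorm_mat(C, C, sdw), Wk = rnorm_mat(C, C, sdw),
       Wv = rnorm_mat(C, C, sdw),
       Wo = if (zero) matrix(0, C, C) else rnorm_mat(C, C, 0.02),
       bo = numeric(C), K = as.integer(K), sw = as.integer(sw))
}

# tape core; x: (B*H*W) x C
.csa <- function(tp, x, p, B, H, W) {
  st <- strip_idx(B, H, W, .val_int(p$sw))
  op_csa(tp, x, p$Wq, p$Wk, p$Wv, p$Wo, p$bo, st$h, st$v, .val_int(p$K))
}

.val_int <- function(x) as.integer(.val(x))

#' Cross-shape self-attention over a feature map
#'
#' Heads `1..K/2` attend within horizontal strips of `sw` rows, heads
#' `K/2+1..K` within vertical strips of `sw` columns; per-position head
#' outputs are concatenated and projected by `Wo`. With `sw` equal to the
#' full extent this reduces exactly to standard multi-head self-attention
#' over all `H*W` tokens.
#'
#' @param X `H x W x C` feature array.
#' @param params parameters from [csaParams()].
#' @return `H x W x C` array.
#' @export
csa <- function(X, params) {
  d <- dim(X)
  out <- .csa(NULL, fm_to_tokens(X), params, 1L, d[1], d[2])
  tokens_to_fm(out, d[1], d[2])
}

#' Construct cross-shape transformer block parameters
#'
#' @inheritParams csaParams
#' @param mlp_ratio hidden-width multiplier of the two-layer GELU MLP.
#' @return nested parameter list (layer norms, attention, MLP).
#' @export
cstParams <- function(C, K, sw = 3L, mlp_ratio = 4, zero = FALSE) {
  hid <- as.integer(round(mlp_ratio * C))
  sdw <- if (zero) 0 else 0.02
  list(ln1_g = rep(1, C), ln1_b = numeric(C),
       attn = csaParams(C, K, sw, zero),
       ln2_g = rep(1, C), ln2_b = numeric(C),
       W1 = rnorm_mat(C, hid, sdw), b1 = numeric(hid),
       W2 = matrix(0, hid, C), b2 = numeric(C))
}

# pre-norm block: X + CSA(LN(X)), then + MLP(LN(.))
.cst_block <- function(tp, x, p, B, H, W) {
  a <- .csa(tp, op_layernorm(tp, x, p$ln1_g, p$ln1_b), p$attn, B, H, W)
  x1 <- op_add(tp, x, a)
  m <- op_linear(tp, op_gelu(tp, op_linear(
    tp, op_layernorm(tp, x1, p$ln2_g, p$ln2_b), p$W1, p$b1)), p$W2, p$b2)
  op_add(tp, x1, m)
}

#' Cross-shape transformer block
#'
#' Two pre-norm residual sublayers: cross-shape self-attention and a
#' two-layer GELU MLP, i.e. `X' = CSA(LN(X)) + X`, `Y = MLP(LN(X')) + X'`.
#'
#' @param X `H x W x C` feature array.
#' @param params parameters from [cstParams()].
#' @return `H x W x C` array.
#' @export
cstBlock <- function(X, params) {
  d <- dim(X)
  out <- .cst_block(NULL, fm_to_tokens(X), params, 1L, d[1], d[2])
  tokens_to_fm(out, d[1], d[2])
}
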