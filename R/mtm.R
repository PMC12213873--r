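# ---------------------------------------------------------------------------
# Mamba-Transformer merge: directional average pooling, four fully
# connected reduction branches, and a rank-1-per-channel spatial attention
# map gating the fused features (coordinate-attention lineage).
# ---------------------------------------------------------------------------

#' Directional average pooling
#'
#' Compresses a feature map into a per-row profile (mean over each row)
#' and a per-column profile (mean over each column), per channel.
#'
#' @param X `H x W x C` feature array.
#' @return list with `Z_h` (`H x C`) and `Z_w` (`W x C`).
#' @export
directionalPool <- function(X) {
  d <- dim(X)
  po <- pool_ops(1L, d[1], d[2])
  tok <- fm_to_tokens(X)
  list(Z_h = as.matrix(po$Sh %*% tok), Z_w = as.matrix(po$Sw %*% tok))
}

#' Construct parameters for the merge module
#'
#' @param C channel width of each input branch.
#' @param square use the square-map formulation (`H == W`; pooled profiles
#'   concatenated along channels, branches `2C -> C/2`). With
#'   `square = FALSE` profiles are concatenated along the length axis and
#'   the branches map `C -> C/4`.
#' @param zero zero-initialize all weights.
#' @param gate include the attention gate (disabling it leaves the plain
#'   pointwise fusion, the ablation baseline).
#' @return nested parameter list.
#' @export
mtmParams <- function(C, square = TRUE, zero = FALSE, gate = TRUE) {
  if (square && C %% 2L != 0L)
    stop("mtmParams: C must be divisible by 2")
  if (!square && C %% 4L != 0L)
    stop("mtmParams: C must be divisible by 4")
  sdw <- if (zero) 0 else 0.02
  din <- if (square) 2L * C else C
  dout <- if (square) C %/% 2L else C %/% 4L
  list(Wp = rnorm_mat(2L * C, C, sdw), bp = numeric(C),
       branches = lapply(1:4, function(i)
         list(W = rnorm_mat(din, dout, sdw), b = numeric(dout))),
       square = square, use_gate = gate)
}

# attention map from pooled profiles; Zh: (B*H) x C, Zw: (B*W) x C
.mtm_map <- function(tp, Zh, Zw, p, B, H, W) {
  C <- ncol(.val(Zh))
  if (isTRUE(p$square)) {
    stopifnot(H == W)
    Z <- op_concat_cols(tp, list(Zh, Zw))
    fs <- lapply(p$branches, function(br)
      op_gelu(tp, op_linear(tp, Z, br$W, br$b)))
    Zo <- op_concat_cols(tp, fs)
    Orow <- op_colselect(tp, Zo, seq_len(C))
    Ocol <- op_colselect(tp, Zo, C + seq_len(C))
  } else {
    Z <- op_rowbind(tp, Zh, Zw)
    fs <- lapply(p$branches, function(br)
      op_gelu(tp, op_linear(tp, Z, br$W, br$b)))
    Zo <- op_concat_cols(tp, fs)
    Orow <- op_rowgather(tp, Zo, seq_len(B * H))
    Ocol <- op_rowgather(tp, Zo, B * H + seq_len(B * W))
  }
  rc <- rc_idx(B, H, W)
  op_outer_rc(tp, Orow, Ocol, rc$h, rc$w)
}

#' Rank-1 spatial attention map from pooled profiles
#'
#' Concatenates the two directional profiles, reduces them through four
#' fully connected GELU branches to a combined vector, splits it into a
#' row-indexed and a column-indexed half, and forms
#' `O[h, w, c] = O_row[h, c] * O_col[w, c]`. Every channel slice of `O`
#' therefore has matrix rank at most 1 by construction.
#'
#' @param Z_h `H x C` row profile, `Z_w` `W x C` column profile (from
#'   [directionalPool()]).
#' @param params parameters from [mtmParams()].
#' @return `H x W x C` attention map (pre-sigmoid).
#' @export
mtmAttentionMap <- function(Z_h, Z_w, params) {
  H <- nrow(Z_h); W <- nrow(Z_w)
  O <- .mtm_map(NULL, as.matrix(Z_h), as.matrix(Z_w), params, 1L, H, W)
  tokens_to_fm(O, H, W)
}

.mtm <- function(tp, et, em, p, B, H, W) {
  X <- op_linear(tp, op_concat_cols(tp, list(et, em)), p$Wp, p$bp)
  if (!isTRUE(p$use_gate)) return(X)
  po <- pool_ops(B, H, W)
  Zh <- op_spmm(tp, po$Sh, X)
  Zw <- op_spmm(tp, po$Sw, X)
  O <- .mtm_map(tp, Zh, Zw, p, B, H, W)
  op_add(tp, op_mul(tp, X, op_sigmoid(tp, O)), X)
}

#' Merge transformer and Mamba branch features
#'
#' The two same-shaped stage outputs are channel-concatenated and fused by
#' a pointwise projection back to `C`; directional pooling and the four
#' reduction branches then produce the rank-1 attention map `O`, and the
#' output is the gated residual `X * sigmoid(O) + X` (so a zero map leaves
#' `1.5 * X`). Input and output shapes are identical.
#'
#' @param E_T,E_M `H x W x C` feature arrays from the transformer and
#'   Mamba branches.
#' @param params parameters from [mtmParams()].
#' @return `H x W x C` fused array.
#' @export
mtmFuse <- function(E_T, E_M, params) {
  d <- dim(E_T)
  if (!identical(dim(E_T), dim(E_M)))
    stop("mtmFuse: E_T and E_M must have identical shape")
  out <- .mtm(NULL, fm_to_tokens(E_T), fm_to_tokens(E_M), params,
              1L, d[1], d[2])
  tokens_to_fm(out, d[1], d[2])
}
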