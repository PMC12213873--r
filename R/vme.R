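# ---------------------------------------------------------------------------
# Vision Mamba encoder stage: patch embedding, positional table, stacked
# bidirectional Vim blocks, and patch merging back to a feature map.
# Tokens scan in row-major order (left-to-right, top-to-bottom) forward and
# exact reverse backward.
# ---------------------------------------------------------------------------

reflect_pad_hw <- function(x, Hp, Wp) {
  d <- dim(x)
  ih <- c(seq_len(d[1]), rev(seq_len(d[1])))[seq_len(Hp)]
  iw <- c(seq_len(d[2]), rev(seq_len(d[2])))[seq_len(Wp)]
  x[ih, iw, , drop = FALSE]
}

#' Embed a feature map into a token sequence
#'
#' Splits the map into non-overlapping `P x P` patches (row-major order),
#' flattens each patch (within-patch row-major, channel-last) and projects
#' it linearly to `D` dimensions; a learned positional table is then
#' added. In segmentation mode no class token is used; an optional class
#' token is supported for completeness.
#'
#' @param x `H x W x C` feature array. Extents not divisible by `P` are
#'   reflect-padded up to the next multiple when `pad = TRUE`, otherwise
#'   an error is raised.
#' @param P patch size.
#' @param D embedding dimension.
#' @param W projection matrix `(P^2*C) x D`; identity when `NULL` and
#'   `P^2*C == D`.
#' @param pos_embed `J x D` positional table (`(J+1) x D` with a class
#'   token); zeros when `NULL`.
#' @param cls_token optional length-`D` class token vector.
#' @param pad reflect-pad non-divisible extents.
#' @return object of class `TokenSequence`: list with `tokens` (`J x D`),
#'   `grid_shape`, `patch_size`, `pos_embed`, `cls_token`, and the
#'   original `crop` extents.
#' @export
patchEmbed <- function(x, P, D, W = NULL, pos_embed = NULL,
                       cls_token = NULL, pad = TRUE) {
  d <- dim(x)
  if (d[1] %% P != 0 || d[2] %% P != 0) {
    if (!pad) stop("patchEmbed: extent not divisible by patch size")
    x <- reflect_pad_hw(x, ceiling(d[1] / P) * P, ceiling(d[2] / P) * P)
  }
  dp <- dim(x)
  rows <- dp[1] %/% P; cols <- dp[2] %/% P; C <- dp[3]
  J <- rows * cols
  if (is.null(W)) {
    if (P * P * C != D)
      stop("patchEmbed: need a projection matrix when P^2*C != D")
    W <- diag(D)
  }
  patches <- matrix(0, J, P * P * C)
  for (j in seq_len(J)) {
    r <- (j - 1L) %/% cols; cc <- (j - 1L) %% cols
    blk <- x[r * P + seq_len(P), cc * P + seq_len(P), , drop = FALSE]
    # within-patch row-major (w fastest), channel fastest of all
    patches[j, ] <- as.vector(aperm(blk, c(3, 2, 1)))
  }
  tokens <- patches %*% W
  has_cls <- !is.null(cls_token)
  if (is.null(pos_embed)) pos_embed <- matrix(0, J + has_cls, D)
  if (nrow(pos_embed) != J + has_cls)
    stop("patchEmbed: pos_embed first axis must be J (+1 with class token)")
  if (has_cls) tokens <- rbind(matrix(cls_token, 1), tokens)
  tokens <- tokens + pos_embed
  structure(list(tokens = tokens, grid_shape = c(rows, cols),
                 patch_size = P, pos_embed = pos_embed,
                 cls_token = cls_token, crop = c(d[1], d[2])),
            class = "TokenSequence")
}

#' Merge a token sequence back into a feature map
#'
#' Inverse spatial bookkeeping of [patchEmbed()]: tokens are laid out on
#' their `rows x cols` grid in the same row-major order; a class token, if
#' present, is discarded. No un-projection is applied (tokens become the
#' channels of the map).
#'
#' @param t `TokenSequence` from [patchEmbed()] (or a compatible list).
#' @return `rows x cols x D` feature array.
#' @export
patchMerge <- function(t) {
  tokens <- t$tokens
  if (!is.null(t$cls_token)) tokens <- tokens[-1, , drop = FALSE]
  g <- t$grid_shape
  if (nrow(tokens) != g[1] * g[2])
    stop("patchMerge: token count does not match grid shape")
  tokens_to_fm(tokens, g[1], g[2])
}

#' Construct parameters for one Vision-Mamba encoder stage
#'
#' The stage operates on pixel tokens (`P = 1`): a learned `C x C` token
#' projection (identity-initialized), a per-stage zero-initialized
#' positional table over the stage's own `J = H*W` grid, and `depth`
#' bidirectional Vim blocks.
#'
#' @param C channel width of the stage.
#' @param J number of tokens (stage `H * W`).
#' @param depth number of Vim blocks.
#' @param d_state,expand,k selective-SSM dimensions, see [vimParams()].
#' @param zero zero-initialize all block weights.
#' @return nested parameter list.
#' @export
vmeStageParams <- function(C, J, depth, d_state = 16L, expand = 2L,
                           k = 4L, zero = FALSE) {
  list(W_embed = diag(C), b_embed = numeric(C),
       epos = matrix(0, J, C),
       blocks = lapply(seq_len(depth), function(i)
         vimParams(C, d_state, expand, k, zero)))
}

.vme_stage <- function(tp, x, p, B, H, W) {
  J <- H * W
  tok <- op_linear(tp, x, p$W_embed, p$b_embed)
  ep <- if (B == 1L) p$epos else
    op_rowgather(tp, p$epos, rep(seq_len(J), B))
  tok <- op_add(tp, tok, ep)
  seqlens <- rep(J, B)
  for (blk in p$blocks) tok <- .vim_block(tp, tok, blk, seqlens)
  tok
}

#' Vision-Mamba encoder stage
#'
#' Tokenizes the map at `P = 1` (linear projection plus learned positional
#' table), applies `depth` bidirectional Vim blocks with residual
#' connections, and merges back to a feature map of the same spatial size.
#'
#' @param X `H x W x C` feature array.
#' @param params parameters from [vmeStageParams()].
#' @return `H x W x C` array.
#' @export
vmeStage <- function(X, params) {
  d <- dim(X)
  if (nrow(params$epos) != d[1] * d[2])
    stop("vmeStage: positional table does not match the input grid")
  out <- .vme_stage(NULL, fm_to_tokens(X), params, 1L, d[1], d[2])
  tokens_to_fm(out, d[1], d[2])
}
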