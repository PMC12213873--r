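# ---------------------------------------------------------------------------
# Composite differentiable operations. Each computes the forward value on
# plain matrices and records one tape node with an analytic adjoint.
# Token convention throughout: a feature map of B samples at H x W x C is the
# (B*H*W) x C matrix whose row (b-1)*H*W + (h-1)*W + w holds the channel
# vector at (h, w) of sample b (row-major spatial order).
# ---------------------------------------------------------------------------

op_add <- function(tp, a, b) {
  val <- .val(a) + .val(b)
  .rec(tp, val, function(g) { .addg(a, g); .addg(b, g) })
}

op_mul <- function(tp, a, b) {
  va <- .val(a); vb <- .val(b)
  .rec(tp, va * vb, function(g) { .addg(a, g * vb); .addg(b, g * va) })
}

op_scale <- function(tp, a, s) {
  .rec(tp, .val(a) * s, function(g) .addg(a, g * s))
}

op_sigmoid <- function(tp, a) {
  v <- 1 / (1 + exp(-.val(a)))
  .rec(tp, v, function(g) .addg(a, g * v * (1 - v)))
}

op_silu <- function(tp, a) {
  va <- .val(a)
  s <- 1 / (1 + exp(-va))
  .rec(tp, va * s, function(g) .addg(a, g * s * (1 + va * (1 - s))))
}

op_gelu <- function(tp, a) {
  va <- .val(a)
  ph <- stats::pnorm(va)
  .rec(tp, va * ph, function(g)
    .addg(a, g * (ph + va * exp(-0.5 * va * va) * 0.3989422804014327)))
}

op_softplus <- function(tp, a) {
  va <- .val(a)
  v <- pmax(va, 0) + log1p(exp(-abs(va)))
  .rec(tp, v, function(g) .addg(a, g / (1 + exp(-va))))
}

# x: n x d, W: d x m, b: length-m bias or NULL
op_linear <- function(tp, x, W, b = NULL) {
  vx <- .val(x); vW <- .val(W)
  val <- vx %*% vW
  if (!is.null(b)) val <- val + rep(.val(b), each = nrow(val))
  .rec(tp, val, function(g) {
    .addg(x, g %*% t(vW))
    .addg(W, crossprod(vx, g))
    if (!is.null(b)) .addg(b, colSums(g))
  })
}

# per-row layer normalization with learned gain/offset (length C)
op_layernorm <- function(tp, x, gamma, beta, eps = 1e-5) {
  vx <- .val(x); vg <- .val(gamma)
  mu <- rowMeans(vx)
  xc <- vx - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xh <- xc * inv
  val <- xh * rep(vg, each = nrow(vx)) + rep(.val(beta), each = nrow(vx))
  .rec(tp, val, function(g) {
    dxh <- g * rep(vg, each = nrow(g))
    m1 <- rowMeans(dxh)
    m2 <- rowMeans(dxh * xh)
    .addg(x, inv * (dxh - m1 - xh * m2))
    .addg(gamma, colSums(g * xh))
    .addg(beta, colSums(g))
  })
}

# gather rows by index; idx == 0 yields a zero row (used for padding)
op_rowgather <- function(tp, x, idx) {
  vx <- .val(x)
  xp <- rbind(0, vx)
  val <- xp[idx + 1L, , drop = FALSE]
  nr <- nrow(vx)
  .rec(tp, val, function(g) {
    v <- idx > 0L
    gs <- rowsum(g[v, , drop = FALSE], group = idx[v])
    dx <- matrix(0, nr, ncol(g))
    dx[as.integer(rownames(gs)), ] <- gs
    .addg(x, dx)
  })
}

op_colselect <- function(tp, x, cols) {
  vx <- .val(x)
  val <- vx[, cols, drop = FALSE]
  nc <- ncol(vx)
  .rec(tp, val, function(g) {
    dx <- matrix(0, nrow(g), nc)
    dx[, cols] <- g
    .addg(x, dx)
  })
}

op_concat_cols <- function(tp, xs) {
  vals <- lapply(xs, .val)
  widths <- vapply(vals, ncol, 1L)
  val <- do.call(cbind, vals)
  .rec(tp, val, function(g) {
    off <- 0L
    for (i in seq_along(xs)) {
      .addg(xs[[i]], g[, off + seq_len(widths[i]), drop = FALSE])
      off <- off + widths[i]
    }
  })
}

op_rowbind <- function(tp, a, b) {
  va <- .val(a); vb <- .val(b)
  na <- nrow(va)
  .rec(tp, rbind(va, vb), function(g) {
    .addg(a, g[seq_len(na), , drop = FALSE])
    .addg(b, g[-seq_len(na), , drop = FALSE])
  })
}

# multiply by a constant sparse matrix (bilinear resize, directional pooling)
op_spmm <- function(tp, S, x) {
  vx <- .val(x)
  val <- as.matrix(S %*% vx)
  .rec(tp, val, function(g) .addg(x, as.matrix(Matrix::crossprod(S, g))))
}

# O[t, c] = R[hidx[t], c] * Cc[widx[t], c]  (rank-1 per-channel map)
op_outer_rc <- function(tp, R, Cc, hidx, widx) {
  vR <- .val(R); vC <- .val(Cc)
  Re <- vR[hidx, , drop = FALSE]
  Ce <- vC[widx, , drop = FALSE]
  .rec(tp, Re * Ce, function(g) {
    dR <- rowsum(g * Ce, group = hidx)
    dC <- rowsum(g * Re, group = widx)
    gR <- matrix(0, nrow(vR), ncol(vR)); gR[as.integer(rownames(dR)), ] <- dR
    gC <- matrix(0, nrow(vC), ncol(vC)); gC[as.integer(rownames(dC)), ] <- dC
    .addg(R, gR); .addg(Cc, gC)
  })
}

# standard k x k convolution through im2col; idx: N x k^2 neighbor rows
# (0 = zero padding), W: (k^2 * Cin) x Cout
op_conv2d <- function(tp, x, W, b, idx) {
  vx <- .val(x); vW <- .val(W)
  cin <- ncol(vx); kk <- ncol(idx); n <- nrow(idx)
  xp <- rbind(0, vx)
  cols <- matrix(0, n, kk * cin)
  for (j in seq_len(kk)) {
    cols[, (j - 1L) * cin + seq_len(cin)] <- xp[idx[, j] + 1L, , drop = FALSE]
  }
  val <- cols %*% vW
  if (!is.null(b)) val <- val + rep(.val(b), each = n)
  .rec(tp, val, function(g) {
    .addg(W, crossprod(cols, g))
    if (!is.null(b)) .addg(b, colSums(g))
    dcols <- g %*% t(vW)
    dx <- matrix(0, nrow(vx), cin)
    for (j in seq_len(kk)) {
      v <- idx[, j] > 0L
      blk <- dcols[v, (j - 1L) * cin + seq_len(cin), drop = FALSE]
      tgt <- idx[v, j]
      dx[tgt, ] <- dx[tgt, ] + blk
    }
    .addg(x, dx)
  })
}

# depthwise k x k (or causal 1-d) convolution; w: k^2 x C per-channel taps
op_dwconv <- function(tp, x, w, b, idx) {
  vx <- .val(x); vw <- .val(w)
  kk <- ncol(idx); n <- nrow(idx); C <- ncol(vx)
  xp <- rbind(0, vx)
  val <- matrix(0, n, C)
  for (j in seq_len(kk)) {
    val <- val + xp[idx[, j] + 1L, , drop = FALSE] *
      rep(vw[j, ], each = n)
  }
  if (!is.null(b)) val <- val + rep(.val(b), each = n)
  .rec(tp, val, function(g) {
    dw <- matrix(0, kk, C)
    dx <- matrix(0, nrow(vx), C)
    for (j in seq_len(kk)) {
      xs <- xp[idx[, j] + 1L, , drop = FALSE]
      dw[j, ] <- colSums(g * xs)
      v <- idx[, j] > 0L
      tgt <- idx[v, j]
      dx[tgt, ] <- dx[tgt, ] + g[v, , drop = FALSE] * rep(vw[j, ], each = sum(v))
    }
    .addg(w, dw)
    if (!is.null(b)) .addg(b, colSums(g))
    .addg(x, dx)
  })
}

# selective state-space scan (Rcpp kernel); A = -exp(A_log)
op_scan <- function(tp, x, delta, Bm, Cm, A_log, Dskip, seqlens) {
  vA_log <- .val(A_log)
  A <- -exp(vA_log)
  vx <- .val(x); vd <- .val(delta); vB <- .val(Bm); vC <- .val(Cm)
  vD <- .val(Dskip)
  fw <- scan_forward_cpp(vx, vd, vB, vC, A, vD, as.integer(seqlens),
                         !is.null(tp))
  .rec(tp, fw$y, function(g) {
    bw <- scan_backward_cpp(vx, vd, vB, vC, A, vD, as.integer(seqlens),
                            fw$H, fw$Ab, g)
    .addg(x, bw$dx)
    .addg(delta, bw$ddelta)
    .addg(Bm, bw$dB)
    .addg(Cm, bw$dC)
    .addg(A_log, bw$dA * A)      # chain through A = -exp(A_log)
    .addg(Dskip, as.numeric(bw$dD))
  })
}

# cross-shape multi-head attention core. xn: N x C (already normalized);
# strips_h / strips_v: lists of integer row-index vectors (one per strip,
# batch offsets included). Heads 1..K/2 attend within horizontal strips,
# heads K/2+1..K within vertical strips; per-head width dk = C/K.
op_csa <- function(tp, xn, Wq, Wk, Wv, Wo, bo, strips_h, strips_v, K) {
  vx <- .val(xn)
  C <- ncol(vx); dk <- C %/% K
  scale <- 1 / sqrt(dk)
  Q <- vx %*% .val(Wq); Km <- vx %*% .val(Wk); V <- vx %*% .val(Wv)
  out <- matrix(0, nrow(vx), C)
  Asaved <- vector("list", K)
  for (k in seq_len(K)) {
    cols <- (k - 1L) * dk + seq_len(dk)
    strips <- if (k <= K %/% 2) strips_h else strips_v
    Ak <- vector("list", length(strips))
    for (s in seq_along(strips)) {
      ii <- strips[[s]]
      Qs <- Q[ii, cols, drop = FALSE]
      Ks <- Km[ii, cols, drop = FALSE]
      sc <- tcrossprod(Qs, Ks) * scale
      sc <- sc - sc[cbind(seq_len(nrow(sc)), max.col(sc, "first"))]
      ex <- exp(sc)
      A <- ex / rowSums(ex)
      out[ii, cols] <- A %*% V[ii, cols, drop = FALSE]
      Ak[[s]] <- A
    }
    Asaved[[k]] <- Ak
  }
  vWo <- .val(Wo)
  val <- out %*% vWo + rep(.val(bo), each = nrow(out))
  .rec(tp, val, function(g) {
    .addg(Wo, crossprod(out, g))
    .addg(bo, colSums(g))
    dout <- g %*% t(vWo)
    dQ <- matrix(0, nrow(vx), C); dK <- dQ; dV <- dQ
    for (k in seq_len(K)) {
      cols <- (k - 1L) * dk + seq_len(dk)
      strips <- if (k <= K %/% 2) strips_h else strips_v
      for (s in seq_along(strips)) {
        ii <- strips[[s]]
        A <- Asaved[[k]][[s]]
        go <- dout[ii, cols, drop = FALSE]
        Vs <- V[ii, cols, drop = FALSE]
        dA <- tcrossprod(go, Vs)
        dV[ii, cols] <- dV[ii, cols] + crossprod(A, go)
        dS <- A * (dA - rowSums(dA * A))
        dQ[ii, cols] <- dS %*% Km[ii, cols, drop = FALSE] * scale
        dK[ii, cols] <- crossprod(dS, Q[ii, cols, drop = FALSE]) * scale
      }
    }
    .addg(Wq, crossprod(vx, dQ))
    .addg(Wk, crossprod(vx, dK))
    .addg(Wv, crossprod(vx, dV))
    .addg(xn, dQ %*% t(.val(Wq)) + dK %*% t(.val(Wk)) + dV %*% t(.val(Wv)))
  })
}

# combined BCE-with-logits + Dice objective on a flat logit vector
op_seg_loss <- function(tp, logits, target, alpha = 1, beta = 1, eps = 1) {
  z <- as.numeric(.val(logits))
  gt <- as.numeric(target)
  n <- length(z)
  p <- 1 / (1 + exp(-z))
  bce <- mean(pmax(z, 0) - z * gt + log1p(exp(-abs(z))))
  spg <- sum(p * gt); sp <- sum(p); sg <- sum(gt)
  num <- 2 * spg + eps; den <- sp + sg + eps
  dice <- 1 - num / den
  val <- alpha * bce + beta * dice
  .rec(tp, val, function(g) {
    dbce <- (p - gt) / n
    ddice_dp <- -(2 * gt * den - num) / den^2
    dz <- alpha * dbce + beta * ddice_dp * p * (1 - p)
    .addg(logits, matrix(as.numeric(g) * dz, ncol = 1))
  })
}

op_sum <- function(tp, x) {
  vx <- .val(x)
  .rec(tp, sum(vx), function(g) .addg(x, array(g, dim = dim0(vx))))
}
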