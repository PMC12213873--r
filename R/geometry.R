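# ---------------------------------------------------------------------------
# Structural constants: neighbor index tables, strip partitions, sparse
# bilinear-resize and directional-pooling operators. All cached per shape.
# ---------------------------------------------------------------------------

# H x W x C array  <->  (H*W) x C token matrix, row-major (w fastest)
fm_to_tokens <- function(a) {
  d <- dim(a)
  if (length(d) == 2L) d <- c(d, 1L)
  matrix(aperm(array(a, d), c(2, 1, 3)), d[1] * d[2], d[3])
}

tokens_to_fm <- function(m, H, W) {
  C <- ncol(m)
  aperm(array(m, c(W, H, C)), c(2, 1, 3))
}

# neighbor index table for same-padded k x k convolution, batched
conv_idx <- function(B, H, W, k) {
  cached(sprintf("conv:%d:%d:%d:%d", B, H, W, k), function() {
    r <- k %/% 2L
    off <- expand.grid(dw = -r:(k - 1L - r), dh = -r:(k - 1L - r))
    h <- rep(seq_len(H), each = W)
    w <- rep(seq_len(W), H)
    idx <- matrix(0L, H * W, k * k)
    for (j in seq_len(k * k)) {
      hh <- h + off$dh[j]; ww <- w + off$dw[j]
      ok <- hh >= 1L & hh <= H & ww >= 1L & ww <= W
      idx[ok, j] <- (hh[ok] - 1L) * W + ww[ok]
    }
    if (B == 1L) return(idx)
    do.call(rbind, lapply(0:(B - 1L), function(b) {
      ifelse(idx > 0L, idx + b * H * W, 0L)
    }))
  })
}

# causal taps for depthwise 1-d convolution over concatenated segments;
# column j holds index of x[t - k + j] (0 before segment start)
causal_idx <- function(seqlens, k) {
  key <- sprintf("causal:%s:%d", paste(seqlens, collapse = ","), k)
  cached(key, function() {
    L <- sum(seqlens)
    idx <- matrix(0L, L, k)
    off <- 0L
    for (len in seqlens) {
      t <- seq_len(len)
      for (j in seq_len(k)) {
        src <- t - k + j
        ok <- src >= 1L
        idx[off + t[ok], j] <- off + src[ok]
      }
      off <- off + len
    }
    idx
  })
}

# per-segment order reversal (bidirectional scan)
reverse_idx <- function(seqlens) {
  key <- sprintf("rev:%s", paste(seqlens, collapse = ","))
  cached(key, function() {
    off <- 0L
    out <- integer(sum(seqlens))
    for (len in seqlens) {
      out[off + seq_len(len)] <- off + rev(seq_len(len))
      off <- off + len
    }
    out
  })
}

# strip partition of the token grid: list of row-index vectors per strip.
# Horizontal strips group sw consecutive rows (full width); vertical strips
# group sw consecutive columns. A trailing narrower strip carries the
# remainder, which is equivalent to zero-padding plus key masking.
strip_idx <- function(B, H, W, sw) {
  cached(sprintf("strip:%d:%d:%d:%d", B, H, W, sw), function() {
    mk <- function(extent, along_rows) {
      M <- ceiling(extent / sw)
      strips <- list()
      for (s in seq_len(M)) {
        sel <- ((s - 1L) * sw + 1L):min(s * sw, extent)
        base <- if (along_rows) {
          as.vector(t(outer(sel, seq_len(W), function(h, w) (h - 1L) * W + w)))
        } else {
          as.vector(t(outer(seq_len(H), sel, function(h, w) (h - 1L) * W + w)))
        }
        strips[[s]] <- base
      }
      strips
    }
    sh <- mk(H, TRUE)
    sv <- mk(W, FALSE)
    if (B > 1L) {
      expand <- function(ss) {
        out <- list()
        for (b in 0:(B - 1L)) for (s in ss) out[[length(out) + 1L]] <- s + b * H * W
        out
      }
      sh <- expand(sh); sv <- expand(sv)
    }
    list(h = sh, v = sv)
  })
}

# sparse bilinear interpolation operator (align_corners = FALSE convention)
bilinear_weights_1d <- function(n_in, n_out) {
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  src <- pmin(pmax(src, 0), n_in - 1)
  i0 <- floor(src)
  w1 <- src - i0
  i1 <- pmin(i0 + 1, n_in - 1)
  list(i0 = i0 + 1, i1 = i1 + 1, w0 = 1 - w1, w1 = w1)
}

resize_op <- function(Hin, Win, Hout, Wout, B = 1L) {
  key <- sprintf("rsz:%d:%d:%d:%d:%d", Hin, Win, Hout, Wout, B)
  cached(key, function() {
    rh <- bilinear_weights_1d(Hin, Hout)
    rw <- bilinear_weights_1d(Win, Wout)
    ho <- rep(seq_len(Hout), each = Wout)
    wo <- rep(seq_len(Wout), Hout)
    rows <- (ho - 1L) * Wout + wo
    tri <- function(hi, hw, wi, ww) {
      list(i = rows, j = (hi[ho] - 1L) * Win + wi[wo], x = hw[ho] * ww[wo])
    }
    parts <- list(tri(rh$i0, rh$w0, rw$i0, rw$w0),
                  tri(rh$i0, rh$w0, rw$i1, rw$w1),
                  tri(rh$i1, rh$w1, rw$i0, rw$w0),
                  tri(rh$i1, rh$w1, rw$i1, rw$w1))
    S <- Matrix::sparseMatrix(
      i = unlist(lapply(parts, `[[`, "i")),
      j = unlist(lapply(parts, `[[`, "j")),
      x = unlist(lapply(parts, `[[`, "x")),
      dims = c(Hout * Wout, Hin * Win))
    if (B > 1L) S <- Matrix::bdiag(rep(list(S), B))
    S
  })
}

# directional mean-pooling operators: rows (B*H) x (B*H*W), cols (B*W) x ...
pool_ops <- function(B, H, W) {
  cached(sprintf("pool:%d:%d:%d", B, H, W), function() {
    b <- rep(0:(B - 1L), each = H * W)
    h <- rep(rep(seq_len(H), each = W), B)
    w <- rep(rep(seq_len(W), H), B)
    tok <- seq_len(B * H * W)
    Sh <- Matrix::sparseMatrix(i = b * H + h, j = tok, x = 1 / W,
                               dims = c(B * H, B * H * W))
    Sw <- Matrix::sparseMatrix(i = b * W + w, j = tok, x = 1 / H,
                               dims = c(B * W, B * H * W))
    list(Sh = Sh, Sw = Sw)
  })
}

# row/column index of each token (for the rank-1 outer-product map)
rc_idx <- function(B, H, W) {
  cached(sprintf("rc:%d:%d:%d", B, H, W), function() {
    b <- rep(0:(B - 1L), each = H * W)
    h <- rep(rep(seq_len(H), each = W), B)
    w <- rep(rep(seq_len(W), H), B)
    list(h = b * H + h, w = b * W + w)
  })
}
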