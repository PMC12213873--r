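# Independent oracles and small helpers shared across the suite.

ns <- asNamespace("mtunet")

rnm <- function(...) {
  d <- c(...)
  array(stats::rnorm(prod(d)), d)
}

# naive step-by-step selective-scan recurrence (reference implementation)
naive_scan <- function(x, delta, B, C, A, D) {
  L <- nrow(x); d <- ncol(x); n <- ncol(A)
  y <- matrix(0, L, d)
  h <- matrix(0, d, n)
  hmax <- 0
  for (t in seq_len(L)) {
    for (i in seq_len(d)) {
      ab <- exp(delta[t, i] * A[i, ])
      h[i, ] <- ab * h[i, ] + delta[t, i] * B[t, ] * x[t, i]
      y[t, i] <- sum(C[t, ] * h[i, ]) + D[i] * x[t, i]
    }
    hmax <- max(hmax, max(abs(h)))
  }
  list(y = y, hmax = hmax)
}

# vanilla multi-head self-attention over a flat token matrix
vanilla_mha <- function(Xm, p, K) {
  C <- ncol(Xm); dk <- C / K
  out <- matrix(0, nrow(Xm), C)
  for (k in seq_len(K)) {
    cols <- (k - 1) * dk + seq_len(dk)
    Q <- Xm %*% p$Wq[, cols]; Kk <- Xm %*% p$Wk[, cols]
    V <- Xm %*% p$Wv[, cols]
    sc <- Q %*% t(Kk) / sqrt(dk)
    sc <- sc - apply(sc, 1, max)
    A <- exp(sc) / rowSums(exp(sc))
    out[, cols] <- A %*% V
  }
  out %*% p$Wo + rep(p$bo, each = nrow(Xm))
}

# full-grid attention with -Inf mask outside a strip (brute-force oracle)
masked_attention <- function(Xm, Wq, Wk, Wv, keep) {
  Q <- Xm %*% Wq; K <- Xm %*% Wk; V <- Xm %*% Wv
  dk <- ncol(Q)
  sc <- Q %*% t(K) / sqrt(dk)
  sc[, !keep] <- -Inf
  sc <- sc - apply(sc, 1, max)
  A <- exp(sc) / rowSums(exp(sc))
  (A %*% V)[keep, , drop = FALSE]
}

fm2m <- function(a) ns$fm_to_tokens(a)

rel_err <- function(a, b) max(abs(a - b)) / max(1e-12, max(abs(b)))

# finite-difference gradient check of a composite op; f(tape, node_list)
gradcheck_op <- function(f, inputs, eps = 1e-5, npick = 6) {
  w <- NULL
  lossf <- function(vals) {
    tp <- ns$new_tape()
    nodes <- lapply(vals, ns$leaf)
    out <- f(tp, nodes)
    if (is.null(w)) w <<- array(stats::rnorm(length(out$val)),
                                dim = ns$dim0(out$val))
    l <- ns$op_sum(tp, ns$op_mul(tp, out, w))
    list(l = l, tp = tp, nodes = nodes)
  }
  r <- lossf(inputs)
  ns$backward(r$tp, r$l)
  errs <- c()
  for (j in seq_along(inputs)) {
    v <- inputs[[j]]
    if (!is.double(v)) next
    ga <- r$nodes[[j]]$grad
    for (i in sample(length(v), min(npick, length(v)))) {
      vp <- v; vp[i] <- vp[i] + eps
      vm <- v; vm[i] <- vm[i] - eps
      ip <- inputs; ip[[j]] <- vp
      im <- inputs; im[[j]] <- vm
      gn <- (lossf(ip)$l$val - lossf(im)$l$val) / (2 * eps)
      errs <- c(errs, abs(gn - ga[i]) / max(1e-6, abs(gn) + abs(ga[i])))
    }
  }
  max(errs)
}

# small test architecture (stage widths divisible by default head counts)
tiny_config <- function(input_size = 64L, depths = 1L) {
  modelConfig(channels = c(8L, 16L, 32L, 64L, 128L), depths = depths,
              heads = c(2L, 4L, 8L, 8L, 16L), input_size = input_size)
}

smoke_samples <- function(n, size = 64L, base_seed = 1000L) {
  sc <- synthConfig(image_size = size)
  lapply(seq_len(n), function(i) genSample(sc, base_seed + i))
}
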