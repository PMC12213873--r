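#' @useDynLib mtunet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# ---------------------------------------------------------------------------
# Minimal reverse-mode tape.
#
# A "tensor" is either a plain numeric matrix/array (no-grad mode) or an
# environment holding $val plus an optional $backfn recorded on a tape.
# Composite operations compute forward values and, when a tape is supplied,
# record a single node with a hand-derived adjoint, keeping the tape short
# even for a full network forward pass.
# ---------------------------------------------------------------------------

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 1024L)
  tp$n <- 0L
  tp
}

#' @noRd
.val <- function(x) if (is.environment(x)) x$val else x

# leaf tensor (parameters, inputs that need gradients)
leaf <- function(val) {
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$grad <- NULL
  e
}

# record an op node on the tape; backfn(g) distributes the upstream grad
.rec <- function(tp, val, backfn) {
  if (is.null(tp)) return(val)
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$grad <- NULL
  e$backfn <- backfn
  n <- tp$n + 1L
  if (n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[n]] <- e
  tp$n <- n
  e
}

.addg <- function(x, g) {
  if (is.environment(x)) {
    x$grad <- if (is.null(x$grad)) g else x$grad + g
  }
  invisible(NULL)
}

# run reverse pass from a scalar node
backward <- function(tp, node, seed = 1) {
  node$grad <- seed
  for (i in seq.int(tp$n, 1L)) {
    e <- tp$nodes[[i]]
    if (!is.null(e$grad) && !is.null(e$backfn)) e$backfn(e$grad)
  }
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# wrap / harvest nested parameter lists
# ---------------------------------------------------------------------------

# Trainable leaves are double arrays; integer/character fields are
# structural configuration and pass through untouched.
wrap_params <- function(p) {
  if (is.list(p)) lapply(p, wrap_params)
  else if (is.double(p)) leaf(p)
  else p
}

grad_of <- function(pn) {
  if (is.list(pn)) lapply(pn, grad_of)
  else if (is.environment(pn)) {
    if (is.null(pn$grad)) array(0, dim = dim0(pn$val)) else pn$grad
  } else NULL
}

dim0 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# flatten a nested list to a named flat list of double arrays (stable order)
flatten_params <- function(p, prefix = "") {
  if (!is.list(p)) {
    if (!is.double(p)) return(list())
    out <- list(p)
    names(out) <- prefix
    return(out)
  }
  nm <- names(p)
  if (is.null(nm)) nm <- as.character(seq_along(p))
  out <- list()
  for (i in seq_along(p)) {
    key <- if (prefix == "") nm[i] else paste0(prefix, ".", nm[i])
    out <- c(out, flatten_params(p[[i]], key))
  }
  out
}

# ---------------------------------------------------------------------------
# cache for structural constants (index matrices, sparse resize operators)
# ---------------------------------------------------------------------------

.cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!is.null(.cache[[key]])) return(.cache[[key]])
  v <- fn()
  assign(key, v, envir = .cache)
  v
}
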