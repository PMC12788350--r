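# Dense neural-network primitives on base-R arrays.
#
# Conventions: feature tensors are column-major arrays with the channel axis
# LAST, typically (B, T, J, C), so `matrix(x, nrow = B*T*J)` yields the
# (rows = site, cols = channel) matrix that BLAS matmuls expect; row order
# is b fastest, then t, then j.  Every `*_fwd` returns list(out, cache);
# every `*_bwd` consumes the upstream gradient plus the cache and returns
# list(dx, grads) with `grads` mirroring the parameter list.  Parameters are
# plain numeric matrices/vectors in nested named lists so the optimizer can
# walk them generically.  Hot elementwise paths call the compiled kernels
# in src/kernels.cpp.

# ---- parameter-tree helpers -------------------------------------------------

# Walks leaves by NAME where available (gradient trees may be assembled in
# a different key order than the parameter tree), by position otherwise.
#' @keywords internal
tree_map <- function(f, a, b = NULL) {
  if (is.list(a)) {
    keys <- if (is.null(names(a))) seq_along(a) else names(a)
    out <- if (is.null(b)) lapply(keys, function(k) tree_map(f, a[[k]]))
           else lapply(keys, function(k) tree_map(f, a[[k]], b[[k]]))
    names(out) <- names(a)
    return(out)
  }
  if (is.null(b)) f(a) else f(a, b)
}

#' @keywords internal
tree_zero <- function(a) tree_map(function(x) x * 0, a)

# Sum two gradient trees (either may be NULL).
#' @keywords internal
tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  tree_map(`+`, a, b)
}

# ---- linear layer -----------------------------------------------------------

# Uniform(-gain/sqrt(fan_in), ..) init, the standard dense-layer default.
# `bias = FALSE` omits the offset (convolutions followed by batch norm,
# where an offset is mathematically redundant).
#' @keywords internal
init_linear <- function(fan_in, fan_out, gain = 1, bias = TRUE) {
  a <- gain / sqrt(fan_in)
  p <- list(W = matrix(stats::runif(fan_in * fan_out, -a, a), fan_in,
                       fan_out))
  if (bias) p$b <- stats::runif(fan_out, -a, a)
  p
}

#' @keywords internal
linear_fwd <- function(xm, p) {
  y <- xm %*% p$W
  if (is.null(p$b)) y else addColVec(y, p$b)
}

# returns list(dx, W=dW, b=db or NULL)
#' @keywords internal
linear_bwd <- function(dym, xm, p) {
  list(dx = dym %*% t(p$W), W = crossprod(xm, dym),
       b = if (is.null(p$b)) NULL else colSums(dym))
}

# assembles a linear-layer gradient entry matching the parameter layout
#' @keywords internal
lin_grads <- function(bwd) {
  g <- list(W = bwd$W)
  if (!is.null(bwd$b)) g$b <- bwd$b
  g
}

# ---- batch normalisation ----------------------------------------------------

# Per-channel over all rows of an (N x C) matrix; running stats kept in a
# separate `state` list so the optimizer never touches them.
#' @keywords internal
init_bn <- function(C) list(gamma = rep(1, C), beta = numeric(C))

#' @keywords internal
init_bn_state <- function(C) list(mean = numeric(C), var = rep(1, C))

# `relu = TRUE` fuses the following ReLU into the same pass (the cached
# xhat is always pre-activation).
#' @keywords internal
bn_fwd <- function(xm, p, state, training, relu = FALSE, momentum = 0.1,
                   eps = 1e-5) {
  n <- nrow(xm)
  if (training) {
    r <- bnTrainC(xm, p$gamma, p$beta, eps, relu)
    unb <- if (n > 1) n / (n - 1) else 1
    state$mean <- (1 - momentum) * state$mean + momentum * r$mean
    state$var <- (1 - momentum) * state$var + momentum * r$var * unb
    inv <- 1 / sqrt(r$var + eps)
    xhat <- r$xhat
    y <- r$out
  } else {
    inv <- 1 / sqrt(state$var + eps)
    xhat <- NULL                              # not needed outside training
    y <- bnEvalC(xm, p$gamma, p$beta, state$mean, state$var, eps, relu)
  }
  list(out = y, cache = list(xhat = xhat, inv = inv, n = n), state = state)
}

#' @keywords internal
bn_bwd <- function(dym, cache, p) {
  r <- bnBwd(dym, cache$xhat, p$gamma * cache$inv)
  list(dx = r$dx, grads = list(gamma = r$dgamma, beta = r$dbeta))
}

# ---- activations ------------------------------------------------------------

#' @keywords internal
relu_fwd <- function(x) reluFwdC(x)

#' @keywords internal
relu_bwd <- function(dy, y) reluBwdMask(dy, y)

# Row-wise softmax of a matrix, numerically stabilised.
#' @keywords internal
softmax_rows <- function(m) {
  rmax <- m[, 1]
  if (ncol(m) > 1) for (j in 2:ncol(m)) rmax <- pmax(rmax, m[, j])
  e <- exp(m - rmax)
  e / rowSums(e)
}

# d logits for y = softmax_rows(logits): rows independent.
#' @keywords internal
softmax_rows_bwd <- function(dy, y) y * (dy - rowSums(dy * y))

# ---- temporal convolution ---------------------------------------------------

# 1-D convolution along the time axis with kernel 3, padding 1 and stride s,
# operating directly on the (B*T*J x Cin) site matrix as a sum of three
# shifted matmuls (no im2col buffer).  W is (3*Cin x Cout): row block k
# holds kernel tap k.
#' @keywords internal
init_tconv <- function(Cin, Cout, bias = TRUE) {
  a <- 1 / sqrt(3 * Cin)
  p <- list(W = matrix(stats::runif(3 * Cin * Cout, -a, a), 3 * Cin, Cout))
  if (bias) p$b <- stats::runif(Cout, -a, a)
  p
}

#' @keywords internal
tconv_out_len <- function(T, stride) (T + 2L - 3L) %/% stride + 1L

# Row indices of frames `tsel` (1-based) in a (B, T, J) site ordering.
#' @keywords internal
site_rows <- function(B, T, J, tsel) {
  as.vector(outer(outer(seq_len(B), B * (tsel - 1L), `+`),
                  B * T * (0:(J - 1L)), `+`))
}

# Per-tap gather/scatter index pairs for one (B, T, J, stride) geometry.
#' @keywords internal
tconv_indices <- function(B, T, J, stride) {
  Tout <- tconv_out_len(T, stride)
  lapply(1:3, function(k) {
    tin <- (0:(Tout - 1L)) * stride + k - 1L   # position in padded input
    sel <- which(tin >= 1L & tin <= T)
    list(ri = site_rows(B, T, J, tin[sel]),
         ro = site_rows(B, Tout, J, sel))
  })
}

#' @keywords internal
tconv_m_fwd <- function(xm, B, T, J, p, stride) {
  Cin <- ncol(xm)
  Cout <- ncol(p$W)
  Tout <- tconv_out_len(T, stride)
  if (stride == 1L) {
    # joint blocks are frame-contiguous: offset dgemm per (tap, joint)
    y <- tconv1FwdC(xm, p$W, B, T, J)
    idx <- NULL
  } else {
    idx <- tconv_indices(B, T, J, stride)
    y <- matrix(0, B * Tout * J, Cout)
    for (k in 1:3) {
      Wk <- p$W[((k - 1L) * Cin + 1L):(k * Cin), , drop = FALSE]
      rowsAddInPlace(y, idx[[k]]$ro, xm[idx[[k]]$ri, , drop = FALSE] %*% Wk)
    }
  }
  if (!is.null(p$b)) y <- addColVec(y, p$b)
  list(out = y, Tout = Tout, idx = idx)
}

# `xm` is the forward input matrix (threaded, not cached); geometry via the
# cached gather indices (stride 2) or (B, T, J) (stride 1).
#' @keywords internal
tconv_m_bwd <- function(dym, xm, idx, p, stride, B, T, J) {
  Cin <- ncol(xm)
  Cout <- ncol(dym)
  if (stride == 1L) {
    r <- tconv1BwdC(dym, xm, p$W, B, T, J)
    dx <- r$dx
    dW <- r$dW
  } else {
    dx <- matrix(0, nrow(xm), Cin)
    dW <- matrix(0, 3 * Cin, Cout)
    for (k in 1:3) {
      rows <- ((k - 1L) * Cin + 1L):(k * Cin)
      Wk <- p$W[rows, , drop = FALSE]
      dys <- dym[idx[[k]]$ro, , drop = FALSE]
      dW[rows, ] <- crossprod(xm[idx[[k]]$ri, , drop = FALSE], dys)
      rowsAddInPlace(dx, idx[[k]]$ri, dys %*% t(Wk))
    }
  }
  g <- list(W = dW)
  if (!is.null(p$b)) g$b <- colSums(dym)
  list(dx = dx, grads = g)
}

# ---- multi-head self-attention ---------------------------------------------

# One scaled dot-product self-attention layer with a residual connection,
# applied independently to N sequences of L tokens with C channels: x is
# (N, L, C).  Heads are contiguous channel blocks of width D = C/H.
# Internals use a (D*H*N) x L token-column layout feeding the compiled
# attScores/attApply kernels.
#' @keywords internal
init_attention <- function(C) {
  list(q = init_linear(C, C), k = init_linear(C, C),
       v = init_linear(C, C), o = init_linear(C, C))
}

#' @keywords internal
to_tokcol <- function(m, N, L, D, H) {
  # (N*L, C) channel-block matrix -> (D*H*N) x L token columns
  x <- aperm(array(m, c(N, L, D, H)), c(3, 4, 1, 2))
  dim(x) <- c(D * H * N, L)
  x
}

#' @keywords internal
from_tokcol <- function(x, N, L, D, H) {
  dim(x) <- c(D, H, N, L)
  m <- aperm(x, c(3, 4, 1, 2))
  dim(m) <- c(N * L, D * H)
  m
}

#' @keywords internal
att_fwd <- function(x, p, H, scale = NULL) {
  d <- dim(x)
  N <- d[1]; L <- d[2]; C <- d[3]
  if (C %% H != 0) stop("channel count ", C, " not divisible by n_heads ", H)
  D <- C %/% H
  if (is.null(scale)) scale <- 1 / sqrt(D)
  xm <- matrix(x, N * L, C)
  Q <- to_tokcol(linear_fwd(xm, p$q), N, L, D, H)
  K <- to_tokcol(linear_fwd(xm, p$k), N, L, D, H)
  V <- to_tokcol(linear_fwd(xm, p$v), N, L, D, H)
  A <- softmax_rows(attScores(Q, K, D) * scale)   # (H*N*L_i) x L_j
  Z <- attApply(V, A, D, FALSE)
  zm <- from_tokcol(Z, N, L, D, H)
  om <- linear_fwd(zm, p$o)
  list(out = x + array(om, d),
       cache = list(xm = xm, Q = Q, K = K, V = V, A = A, zm = zm,
                    dims = c(N, L, C, D, H), scale = scale))
}

#' @keywords internal
att_bwd <- function(dy, cache, p) {
  dd <- cache$dims
  N <- dd[1]; L <- dd[2]; C <- dd[3]; D <- dd[4]; H <- dd[5]
  A <- cache$A
  dym <- matrix(dy, N * L, C)
  bo <- linear_bwd(dym, cache$zm, p$o)
  dZ <- to_tokcol(bo$dx, N, L, D, H)
  dA <- attScores(dZ, cache$V, D)
  dV <- attApply(dZ, A, D, TRUE)
  dS <- softmax_rows_bwd(dA, A) * cache$scale
  dQ <- attApply(cache$K, dS, D, FALSE)
  dK <- attApply(cache$Q, dS, D, TRUE)
  bq <- linear_bwd(from_tokcol(dQ, N, L, D, H), cache$xm, p$q)
  bk <- linear_bwd(from_tokcol(dK, N, L, D, H), cache$xm, p$k)
  bv <- linear_bwd(from_tokcol(dV, N, L, D, H), cache$xm, p$v)
  dxm <- dym + bq$dx + bk$dx + bv$dx
  list(dx = array(dxm, c(N, L, C)),
       grads = list(q = list(W = bq$W, b = bq$b),
                    k = list(W = bk$W, b = bk$b),
                    v = list(W = bv$W, b = bv$b),
                    o = list(W = bo$W, b = bo$b)))
}
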