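# Dual-stream spatio-temporal convolutional backbone.
#
# Each stream stacks three STGCN blocks.  A block is: per-joint 1x1
# channel-mixing ("spatial") convolution -> batch norm -> ReLU -> temporal
# convolution (kernel 3, padding 1, block stride) -> batch norm -> residual
# add -> ReLU.  The spatial stage deliberately carries no skeletal adjacency:
# it is exactly a fully connected transform applied identically at every
# (frame, joint) site.  The residual branch is the identity when shapes
# match, otherwise a strided 1x1 convolution + batch norm.
#
# For speed and memory, streams operate on (B*T*J x C) site matrices
# throughout; tensors are threaded block-to-block rather than duplicated
# into per-block caches, and ReLU masks are recovered from the threaded
# outputs.

#' Configuration of one backbone stream
#'
#' @param in_channels Input channels per joint (3 for positions or Euler
#'   angles, 4 for quaternions).
#' @param block_channels Output channels of the three blocks.
#' @param block_strides Temporal strides of the three blocks.
#' @param batchnorm Logical; disable to drop all batch normalisation.
#' @return A list of class `stream_config`.
#' @export
stream_config <- function(in_channels = 3, block_channels = c(64, 128, 256),
                          block_strides = c(1, 2, 2), batchnorm = TRUE) {
  stopifnot(length(block_channels) == 3, length(block_strides) == 3,
            all(block_strides %in% c(1, 2)))
  structure(list(in_channels = as.integer(in_channels),
                 block_channels = as.integer(block_channels),
                 block_strides = as.integer(block_strides),
                 batchnorm = isTRUE(batchnorm)),
            class = "stream_config")
}

# Convolution offsets are dropped when batch norm follows (its beta makes
# them redundant).
#' @keywords internal
init_block <- function(Cin, Cout, stride, batchnorm) {
  p <- list(sp = init_linear(Cin, Cout, bias = !batchnorm),
            tc = init_tconv(Cout, Cout, bias = !batchnorm))
  s <- list()
  if (batchnorm) {
    p$bn1 <- init_bn(Cout); p$bn2 <- init_bn(Cout)
    s$bn1 <- init_bn_state(Cout); s$bn2 <- init_bn_state(Cout)
  }
  if (Cin != Cout || stride != 1) {
    p$res <- init_linear(Cin, Cout, bias = !batchnorm)
    if (batchnorm) {
      p$bnr <- init_bn(Cout)
      s$bnr <- init_bn_state(Cout)
    }
  }
  list(params = p, state = s)
}

#' @keywords internal
init_stream <- function(cfg) {
  Cin <- c(cfg$in_channels, cfg$block_channels[1:2])
  blocks <- lapply(1:3, function(i)
    init_block(Cin[i], cfg$block_channels[i], cfg$block_strides[i],
               cfg$batchnorm))
  list(params = lapply(blocks, `[[`, "params"),
       state = lapply(blocks, `[[`, "state"))
}

# ---- matrix-centric block ---------------------------------------------------

#' @keywords internal
block_m_fwd <- function(xm, B, T, J, params, state, stride, training) {
  has_bn <- !is.null(params$bn1)
  cache <- list(stride = stride)

  h <- linear_fwd(xm, params$sp)
  if (has_bn) {
    b1 <- bn_fwd(h, params$bn1, state$bn1, training, relu = TRUE)
    state$bn1 <- b1$state; cache$bn1 <- b1$cache
    a <- b1$out
  } else {
    a <- relu_fwd(h)
    cache$a <- a                              # with bn, recomputed in bwd
  }
  tc <- tconv_m_fwd(a, B, T, J, params$tc, stride)
  cache$idx <- tc$idx
  Tout <- tc$Tout
  tm <- tc$out
  if (has_bn) {
    b2 <- bn_fwd(tm, params$bn2, state$bn2, training)
    state$bn2 <- b2$state; cache$bn2 <- b2$cache; tm <- b2$out
  }

  if (is.null(params$res)) {
    rm_ <- xm
  } else {
    rs <- if (stride == 1L) xm
          else xm[site_rows(B, T, J, seq(1L, T, by = stride)), , drop = FALSE]
    rm_ <- linear_fwd(rs, params$res)
    if (has_bn) {
      br <- bn_fwd(rm_, params$bnr, state$bnr, training)
      state$bnr <- br$state; cache$bnr <- br$cache; rm_ <- br$out
    }
  }
  cache$dims <- c(B, T, J, ncol(xm), Tout, ncol(tm))
  list(out = reluSum(tm, rm_), Tout = Tout, cache = cache, state = state)
}

# `xm`/`out` are the block's forward input/output matrices (threaded).
#' @keywords internal
block_m_bwd <- function(dym, xm, out, cache, params) {
  dd <- cache$dims
  B <- dd[1]; T <- dd[2]; J <- dd[3]; Cin <- dd[4]
  has_bn <- !is.null(params$bn1)
  grads <- list()
  dsum <- relu_bwd(dym, out)

  # residual branch
  if (is.null(params$res)) {
    dx_res <- dsum
  } else {
    dr <- dsum
    if (has_bn) {
      bb <- bn_bwd(dr, cache$bnr, params$bnr)
      grads$bnr <- bb$grads; dr <- bb$dx
    }
    if (cache$stride == 1L) {
      lb <- linear_bwd(dr, xm, params$res)
      dx_res <- lb$dx
    } else {
      rows <- site_rows(B, T, J, seq(1L, T, by = cache$stride))
      lb <- linear_bwd(dr, xm[rows, , drop = FALSE], params$res)
      dx_res <- matrix(0, nrow(xm), Cin)
      rowsAddInPlace(dx_res, rows, lb$dx)
    }
    grads$res <- lin_grads(lb)
  }

  # main branch
  dtm <- dsum
  if (has_bn) {
    b2 <- bn_bwd(dtm, cache$bn2, params$bn2)
    grads$bn2 <- b2$grads; dtm <- b2$dx
  }
  a <- if (has_bn)
    scaleShiftRelu(cache$bn1$xhat, params$bn1$gamma, params$bn1$beta)
  else cache$a
  tb <- tconv_m_bwd(dtm, a, cache$idx, params$tc, cache$stride, B, T, J)
  grads$tc <- tb$grads
  da <- relu_bwd(tb$dx, a)
  if (has_bn) {
    b1 <- bn_bwd(da, cache$bn1, params$bn1)
    grads$bn1 <- b1$grads; da <- b1$dx
  }
  sb <- linear_bwd(da, xm, params$sp)
  grads$sp <- lin_grads(sb)
  list(dx = sb$dx + dx_res, grads = grads)
}

#' One STGCN block forward pass
#'
#' @param x Input array of shape `(B, T, J, Cin)`.
#' @param params,state Block parameters and batch-norm running statistics as
#'   produced internally by the model constructor.
#' @param stride Temporal stride (1 or 2).
#' @param training Logical; batch statistics vs running statistics.
#' @return list with `out` of shape `(B, T_out, J, Cout)`,
#'   `T_out = floor((T + 2 - 3)/stride) + 1`, plus `cache` and `state`.
#' @export
stgcn_block <- function(x, params, state, stride, training = FALSE) {
  if (!all(is.finite(x))) stop("non-finite values in block input")
  d <- dim(x)
  r <- block_m_fwd(matrix(x, d[1] * d[2] * d[3], d[4]), d[1], d[2], d[3],
                   params, state, stride, training)
  list(out = array(r$out, c(d[1], r$Tout, d[3], ncol(r$out))),
       cache = r$cache, state = r$state)
}

# Runs the three blocks on the site-matrix representation; `mats` holds the
# threaded block input/output matrices ([[1]] is the stream input, [[4]] the
# stream output).
#' @keywords internal
stream_fwd <- function(x, params, state, cfg, training = FALSE) {
  d <- dim(x)
  B <- d[1]; J <- d[3]
  caches <- vector("list", 3)
  mats <- vector("list", 4)
  mats[[1]] <- matrix(x, B * d[2] * J, d[4])
  Tlen <- d[2]
  Tlens <- numeric(4); Tlens[1] <- Tlen
  for (i in 1:3) {
    r <- block_m_fwd(mats[[i]], B, Tlen, J, params[[i]], state[[i]],
                     cfg$block_strides[i], training)
    Tlen <- r$Tout
    Tlens[i + 1] <- Tlen
    mats[[i + 1]] <- r$out
    caches[[i]] <- r$cache
    state[[i]] <- r$state
  }
  list(mats = mats, caches = caches, state = state,
       geom = list(B = B, J = J, Tlens = Tlens))
}

# `dy` may be a site matrix or a (B, T', J, C) array.
#' @keywords internal
stream_bwd <- function(dy, fwd, params) {
  g <- fwd$geom
  dym <- if (is.matrix(dy)) dy
         else matrix(dy, nrow(fwd$mats[[4]]), ncol(fwd$mats[[4]]))
  grads <- vector("list", 3)
  for (i in 3:1) {
    r <- block_m_bwd(dym, fwd$mats[[i]], fwd$mats[[i + 1]],
                     fwd$caches[[i]], params[[i]])
    dym <- r$dx
    grads[[i]] <- r$grads
  }
  list(dx = array(dym, c(g$B, g$Tlens[1], g$J, ncol(dym))), grads = grads)
}

#' Dual-stream backbone forward pass
#'
#' Runs positions and orientations through their independent streams and
#' concatenates the two outputs along the channel axis.
#'
#' @param positions Array `(B, T, J, Cpos)`.
#' @param orientations Array `(B, T, J, Cori)`; quaternion (4) or Euler (3)
#'   channels.
#' @param model A [d2sta_model] (only its backbone is used).
#' @param training Logical.
#' @return list with `out`: the fused feature array
#'   `(B, T', J, Cpos_out + Cori_out)` (for strides 1,2,2 and T = 100,
#'   T' = 25), plus caches/state for backpropagation.
#' @export
dual_stream_forward <- function(positions, orientations, model,
                                training = FALSE) {
  dp <- dim(positions); do_ <- dim(orientations)
  if (!identical(dp[1:3], do_[1:3]))
    stop("position/orientation streams disagree in (B, T, J): ",
         paste(dp[1:3], collapse = "x"), " vs ",
         paste(do_[1:3], collapse = "x"))
  p <- stream_fwd(positions, model$params$pos, model$state$pos,
                  model$config$pos_stream, training)
  o <- stream_fwd(orientations, model$params$ori, model$state$ori,
                  model$config$ori_stream, training)
  fused_m <- cbind(p$mats[[4]], o$mats[[4]])
  g <- p$geom
  Tp <- g$Tlens[4]
  list(out = array(fused_m, c(g$B, Tp, g$J, ncol(fused_m))),
       fused_m = fused_m, pos = p, ori = o, c_pos = ncol(p$mats[[4]]),
       geom = list(B = g$B, T = Tp, J = g$J))
}
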