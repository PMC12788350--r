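# Full scoring network: dual-stream backbone -> SADG -> spatio-temporal mean
# pooling -> two-layer regression head.  The model object is a plain list
# (class "d2sta_model") holding config, parameters and batch-norm state;
# forward/backward are free functions so training stays functional.

#' Model configuration
#'
#' @param in_pos,in_ori Channels of the position / orientation input (3, and
#'   4 for quaternions or 3 for Euler angles).
#' @param channels Per-block output channels of each backbone stream.
#' @param strides Per-block temporal strides.
#' @param n_groups,n_heads,mask_hidden,attn_scale,stage_order Passed to
#'   [sadg_config()].
#' @param head_hidden Hidden width of the regression head; default is a
#'   quarter of the fused channel count (512 -> 128 at full width).
#' @param score_scale `"unit_interval"` trains on scores/100 (the default;
#'   matches error magnitudes of published results), `"raw_0_100"` trains on
#'   the raw scale.
#' @param batchnorm Enable batch normalisation in the backbone.
#' @param ablation One of `"none"`, `"no_sadg"`, `"mhsa_only"`,
#'   `"position_only"`, `"orientation_only"`.
#' @return list of class `d2sta_config`.
#' @export
model_config <- function(in_pos = 3, in_ori = 4,
                         channels = c(64, 128, 256), strides = c(1, 2, 2),
                         n_groups = 6, n_heads = 8, mask_hidden = 64,
                         attn_scale = NULL,
                         stage_order = c("temporal", "group"),
                         head_hidden = NULL,
                         score_scale = c("unit_interval", "raw_0_100"),
                         batchnorm = TRUE,
                         ablation = c("none", "no_sadg", "mhsa_only",
                                      "position_only", "orientation_only")) {
  ablation <- match.arg(ablation)
  score_scale <- match.arg(score_scale)
  cin_pos <- if (ablation == "orientation_only") in_ori else in_pos
  cin_ori <- if (ablation == "position_only") in_pos else in_ori
  C <- 2L * as.integer(channels[3])
  if (is.null(head_hidden)) head_hidden <- C %/% 4L
  structure(list(
    in_pos = as.integer(in_pos), in_ori = as.integer(in_ori),
    pos_stream = stream_config(cin_pos, channels, strides, batchnorm),
    ori_stream = stream_config(cin_ori, channels, strides, batchnorm),
    sadg = sadg_config(n_groups, n_heads, mask_hidden, attn_scale,
                       stage_order),
    fused_channels = C,
    head_hidden = as.integer(head_hidden),
    score_scale = score_scale,
    batchnorm = isTRUE(batchnorm),
    ablation = ablation
  ), class = "d2sta_config")
}

#' Construct a scoring model
#'
#' @param config A [model_config()].
#' @param seed Optional integer; seeds parameter initialisation.
#' @return Object of class `d2sta_model` with elements `config`, `params`
#'   (nested numeric arrays) and `state` (batch-norm running statistics).
#' @export
init_model <- function(config = model_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  C <- config$fused_channels
  pos <- init_stream(config$pos_stream)
  ori <- init_stream(config$ori_stream)
  params <- list(pos = pos$params, ori = ori$params)
  state <- list(pos = pos$state, ori = ori$state)
  if (config$ablation %in% c("none", "position_only", "orientation_only")) {
    params$sadg <- init_sadg(C, config$sadg)
  } else if (config$ablation == "mhsa_only") {
    params$mhsa <- list(att = init_attention(C), out = init_linear(C, C, gain = 0.1))
  }
  params$head <- list(l1 = init_linear(C, config$head_hidden),
                      l2 = init_linear(config$head_hidden, 1))
  # start the head at the midpoint of the score scale so early epochs are
  # spent on ranking rather than on closing a constant offset
  params$head$l2$b[] <- if (config$score_scale == "unit_interval") 0.5 else 50

  structure(list(config = config, params = params, state = state),
            class = "d2sta_model")
}

#' @export
print.d2sta_model <- function(x, ...) {
  cfg <- x$config
  np <- sum(unlist(tree_map(length, x$params)))
  cat("<d2sta_model>\n")
  cat("  streams : pos", cfg$pos_stream$in_channels, "ch / ori",
      cfg$ori_stream$in_channels, "ch ->",
      paste(cfg$pos_stream$block_channels, collapse = "-"),
      "(strides", paste(cfg$pos_stream$block_strides, collapse = ","), ")\n")
  cat("  fused   :", cfg$fused_channels, "channels\n")
  cat("  sadg    :", if (is.null(x$params$sadg)) "disabled" else
    paste0("G=", cfg$sadg$n_groups, " H=", cfg$sadg$n_heads,
           " d=", cfg$sadg$mask_hidden), "\n")
  cat("  head    :", cfg$fused_channels, "->", cfg$head_hidden, "-> 1\n")
  cat("  ablation:", cfg$ablation, " score scale:", cfg$score_scale, "\n")
  cat("  params  :", format(np, big.mark = ","), "\n")
  invisible(x)
}

#' Mean pooling over time and joints
#'
#' @param z Feature array `(B, T, J, C)`.
#' @return Matrix `(B, C)` of per-sample channel means.
#' @export
pool_spatiotemporal <- function(z) {
  d <- dim(z)
  poolTJC(matrix(z, d[1] * d[2] * d[3], d[4]), d[1], d[2], d[3])
}

#' Regression head
#'
#' Two linear layers with a ReLU between: `W2 %*% relu(W1 x + b1) + b2`.
#'
#' @param x Matrix `(B, C)` of pooled features.
#' @param params list with `l1` (C x hidden) and `l2` (hidden x 1).
#' @return Numeric vector of B predicted scores.
#' @export
regression_head <- function(x, params) {
  if (ncol(x) != nrow(params$l1$W))
    stop("head expects ", nrow(params$l1$W), " input channels, got ", ncol(x))
  h <- relu_fwd(linear_fwd(x, params$l1))
  drop(linear_fwd(h, params$l2))
}

#' @keywords internal
head_fwd <- function(x, params) {
  h <- relu_fwd(linear_fwd(x, params$l1))
  y <- linear_fwd(h, params$l2)
  list(out = drop(y), cache = list(x = x, h = h))
}

#' @keywords internal
head_bwd <- function(dy, cache, params) {
  l2 <- linear_bwd(matrix(dy, ncol = 1), cache$h, params$l2)
  dh <- relu_bwd(l2$dx, cache$h)
  l1 <- linear_bwd(dh, cache$x, params$l1)
  list(dx = l1$dx,
       grads = list(l1 = list(W = l1$W, b = l1$b),
                    l2 = list(W = l2$W, b = l2$b)))
}

#' Half mean-squared-error loss
#'
#' `(1/N) sum_i 0.5 * (yhat_i - y_i)^2`.
#'
#' @param y_hat,y Equal-length numeric vectors.
#' @return Scalar loss.
#' @export
mse_loss <- function(y_hat, y) {
  if (length(y_hat) != length(y))
    stop("length mismatch: ", length(y_hat), " vs ", length(y))
  mean(0.5 * (y_hat - y)^2)
}

# ---- full network forward / backward ---------------------------------------

# Full forward pass on the site-matrix representation.
#' @keywords internal
model_fwd <- function(model, positions, orientations, training = FALSE) {
  cfg <- model$config
  if (cfg$ablation == "position_only") orientations <- positions
  if (cfg$ablation == "orientation_only") positions <- orientations
  p <- stream_fwd(positions, model$params$pos, model$state$pos,
                  cfg$pos_stream, training)
  o <- stream_fwd(orientations, model$params$ori, model$state$ori,
                  cfg$ori_stream, training)
  model$state$pos <- p$state
  model$state$ori <- o$state
  fused_m <- cbind(p$mats[[4]], o$mats[[4]])
  B <- p$geom$B; J <- p$geom$J; Tp <- p$geom$Tlens[4]
  C <- ncol(fused_m)
  cache <- list(pos = p, ori = o, c_pos = ncol(p$mats[[4]]),
                geom = c(B = B, T = Tp, J = J), fused_m = fused_m)
  z_m <- fused_m
  if (!is.null(model$params$sadg)) {
    sg <- sadg_fwd_m(fused_m, B, Tp, J, model$params$sadg, cfg$sadg)
    z_m <- sg$out
    cache$sadg <- sg$cache
    cache$alpha <- sg$cache$alpha
  } else if (!is.null(model$params$mhsa)) {
    tok <- fused_m
    dim(tok) <- c(B * Tp, J, C)                # tokens = joints per (b, t)
    at <- att_fwd(tok, model$params$mhsa$att, cfg$sadg$n_heads,
                  cfg$sadg$scale)
    zm <- matrix(at$out, B * Tp * J, C)
    om <- linear_fwd(zm, model$params$mhsa$out)
    z_m <- fused_m + om
    cache$mhsa <- list(att = at$cache, zm = zm)
  }
  pooled <- poolTJC(z_m, B, Tp, J)
  hd <- head_fwd(pooled, model$params$head)
  cache$head <- hd$cache
  list(y = hd$out, cache = cache, state = model$state)
}

#' @keywords internal
model_bwd <- function(model, cache, dy) {
  cfg <- model$config
  g <- cache$geom
  B <- g["B"]; Tp <- g["T"]; J <- g["J"]
  grads <- list()
  hb <- head_bwd(dy, cache$head, model$params$head)
  grads$head <- hb$grads
  dz_m <- poolBwdC(hb$dx, B, Tp, J)
  if (!is.null(model$params$sadg)) {
    sb <- sadg_bwd_m(dz_m, cache$fused_m, B, Tp, J, cache$sadg,
                     model$params$sadg, cfg$sadg)
    grads$sadg <- sb$grads
    dfused <- sb$dx
  } else if (!is.null(model$params$mhsa)) {
    C <- ncol(cache$fused_m)
    ob <- linear_bwd(dz_m, cache$mhsa$zm, model$params$mhsa$out)
    dtok <- ob$dx
    dim(dtok) <- c(B * Tp, J, C)
    ab <- att_bwd(dtok, cache$mhsa$att, model$params$mhsa$att)
    dfused <- dz_m + matrix(ab$dx, B * Tp * J, C)
    grads$mhsa <- list(att = ab$grads, out = list(W = ob$W, b = ob$b))
  } else {
    dfused <- dz_m
  }
  cp <- cache$c_pos
  pb <- stream_bwd(dfused[, seq_len(cp), drop = FALSE], cache$pos,
                   model$params$pos)
  ob2 <- stream_bwd(dfused[, (cp + 1):ncol(dfused), drop = FALSE],
                    cache$ori, model$params$ori)
  grads$pos <- pb$grads
  grads$ori <- ob2$grads
  if (cfg$ablation %in% c("position_only", "orientation_only")) {
    dx <- pb$dx + ob2$dx
    list(grads = grads,
         dpos = if (cfg$ablation == "position_only") dx else NULL,
         dori = if (cfg$ablation == "orientation_only") dx else NULL)
  } else {
    list(grads = grads, dpos = pb$dx, dori = ob2$dx)
  }
}

#' Predict quality scores
#'
#' Runs the network in evaluation mode (batch-norm running statistics).
#'
#' @param object A `d2sta_model`.
#' @param positions Array `(B, T, J, Cpos)`.
#' @param orientations Array `(B, T, J, Cori)`.
#' @param batch_size Mini-batch size used internally.
#' @param ... Unused.
#' @return Numeric vector of predicted scores on the model's score scale.
#' @export
predict.d2sta_model <- function(object, positions, orientations,
                                batch_size = 32L, ...) {
  n <- dim(positions)[1]
  out <- numeric(n)
  for (s in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    r <- model_fwd(object,
                   positions[s, , , , drop = FALSE],
                   orientations[s, , , , drop = FALSE], training = FALSE)
    out[s] <- r$y
  }
  out
}

#' Average soft group assignment over a dataset
#'
#' @param model A trained `d2sta_model` (with SADG enabled).
#' @param positions,orientations Input arrays for the samples to average
#'   over.
#' @param joint_names Optional J joint names for the result's rownames.
#' @param batch_size Mini-batch size.
#' @return A `J x G` matrix of mean assignment probabilities (rows sum to 1).
#' @export
inspect_groups <- function(model, positions, orientations,
                           joint_names = NULL, batch_size = 32L) {
  if (is.null(model$params$sadg)) stop("model has no SADG module")
  n <- dim(positions)[1]
  acc <- NULL
  for (s in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    r <- model_fwd(model,
                   positions[s, , , , drop = FALSE],
                   orientations[s, , , , drop = FALSE], training = FALSE)
    a <- r$cache$alpha                          # (B, G, J)
    asum <- apply(a, c(3, 2), sum)              # J x G
    acc <- if (is.null(acc)) asum else acc + asum
  }
  m <- acc / n
  colnames(m) <- paste0("group_", seq_len(ncol(m)))
  if (!is.null(joint_names)) rownames(m) <- joint_names
  m
}

#' Attention weights for visualisation
#'
#' Runs the model in evaluation mode and collects the per-stage, per-head
#' attention matrices of the SADG module.
#'
#' @param model A `d2sta_model` with SADG enabled.
#' @param positions,orientations Input arrays for a (small) batch.
#' @return Named list with one `(H, N, L, L)` array per attention stage
#'   (`temporal`: N = B*G sequences of L = T' tokens; `group`: N = B*T'
#'   sequences of L = G tokens), rows normalised to 1.
#' @export
attention_weights <- function(model, positions, orientations) {
  if (is.null(model$params$sadg)) stop("model has no SADG module")
  r <- model_fwd(model, positions, orientations, training = FALSE)
  out <- list()
  for (st in r$cache$sadg$ga$caches) {
    A <- st$att$A
    L <- ncol(A)
    HN <- nrow(A) / L
    H <- model$config$sadg$n_heads
    out[[st$stage]] <- array(A, c(H, HN / H, L, L))
  }
  out
}
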