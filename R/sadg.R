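# Self-Attention for Dynamic Groups (SADG).
#
# Pipeline: motion amplitude (per-joint/channel std over time) -> soft
# group-assignment mask via a 2-layer MLP + softmax over groups ->
# projection of joints onto G functional groups -> two-stage multi-head
# self-attention (temporal tokens within each group, then group tokens at
# each time step) -> back-projection to joints with the same mask -> learned
# C->C output projection -> residual add with the module input.  Zeroing the
# output projection therefore makes the whole module an exact identity,
# which is what the no-SADG ablation equivalence relies on.
#
# Internals run on (B*T*J) x C site matrices (rows b fastest, then t, then
# j) via the compiled kernels; the exported operations accept and return
# the documented (B, T, J/G, C) arrays.

#' SADG configuration
#'
#' @param n_groups Number of functional groups G (soft assignment).
#' @param n_heads Attention heads H; channels must be divisible by H.
#' @param mask_hidden Hidden width d of the mask-generator MLP.
#' @param scale Attention logit scale; default `1/sqrt(C/H)`.
#' @param stage_order Order of the two attention stages; `"temporal"` models
#'   time steps within a group, `"group"` models groups within a time step.
#' @return list of class `sadg_config`.
#' @export
sadg_config <- function(n_groups = 6, n_heads = 8, mask_hidden = 64,
                        scale = NULL, stage_order = c("temporal", "group")) {
  stopifnot(all(stage_order %in% c("temporal", "group")),
            length(stage_order) == 2)
  structure(list(n_groups = as.integer(n_groups),
                 n_heads = as.integer(n_heads),
                 mask_hidden = as.integer(mask_hidden),
                 scale = scale, stage_order = stage_order),
            class = "sadg_config")
}

# The mask generator's output layer is initialised with enough gain that
# group logits start with unit-order dispersion: joints whose motion
# amplitudes differ then receive distinct soft assignments from the first
# forward pass, instead of a collapsed near-argmax-constant softmax that
# the low published learning rate would take many epochs to sharpen.
#' @keywords internal
init_sadg <- function(C, cfg) {
  list(mask = list(l1 = init_linear(C, cfg$mask_hidden),
                   l2 = init_linear(cfg$mask_hidden, cfg$n_groups,
                                    gain = 8)),
       att_t = init_attention(C),
       att_g = init_attention(C),
       out = init_linear(C, C, gain = 0.1))
}

#' Motion amplitude statistic
#'
#' Population standard deviation of every (joint, channel) feature along the
#' temporal axis; the module's proxy for range of motion.
#'
#' @param x Feature array `(B, T, J, C)`.
#' @return Array `(B, J, C)` of non-negative amplitudes.
#' @export
motion_amplitude <- function(x) {
  d <- dim(x)
  r <- timeStdC(matrix(x, d[1] * d[2] * d[3], d[4]), d[1], d[2], d[3])
  array(r$M, c(d[1], d[3], d[4]))
}

#' Soft group-assignment mask
#'
#' Two-stage linear map of the motion amplitude to group logits, followed by
#' a softmax over groups, giving each joint a probability distribution over
#' the G functional groups.
#'
#' @param m Motion amplitude array `(B, J, C)`.
#' @param params list with `l1` (W: C x d, b) and `l2` (W: d x G, b).
#' @return Assignment array alpha `(B, G, J)`; `sum_g alpha[b, g, j] == 1`.
#' @export
group_mask <- function(m, params) {
  d <- dim(m)
  group_mask_fwd(matrix(m, d[1] * d[2], d[3]), d[1], d[2], params)$alpha
}

# `Mm` is the (B*J) x C amplitude matrix, rows b fastest then j.
#' @keywords internal
group_mask_fwd <- function(Mm, B, J, params) {
  if (nrow(params$l1$W) != ncol(Mm))
    stop("mask generator expects ", nrow(params$l1$W), " channels, got ",
         ncol(Mm))
  h <- relu_fwd(linear_fwd(Mm, params$l1))
  logits <- linear_fwd(h, params$l2)
  aljg <- softmax_rows(logits)                # rows (b, j), cols g
  G <- ncol(aljg)
  alpha <- aperm(array(aljg, c(B, J, G)), c(1, 3, 2))
  list(alpha = alpha,
       cache = list(Mm = Mm, h = h, aljg = aljg, B = B, J = J, G = G))
}

# dalpha (B, G, J) -> gradients of mask params and of the amplitude matrix.
#' @keywords internal
group_mask_bwd <- function(dalpha, cache, params) {
  B <- cache$B; J <- cache$J; G <- cache$G
  daljg <- matrix(aperm(dalpha, c(1, 3, 2)), B * J, G)
  dlogits <- softmax_rows_bwd(daljg, cache$aljg)
  l2 <- linear_bwd(dlogits, cache$h, params$l2)
  dh <- relu_bwd(l2$dx, cache$h)
  l1 <- linear_bwd(dh, cache$Mm, params$l1)
  list(dMm = l1$dx,
       grads = list(l1 = list(W = l1$W, b = l1$b),
                    l2 = list(W = l2$W, b = l2$b)))
}

#' Project joint features onto functional groups
#'
#' `Xg[b,t,g,c] = sum_j alpha[b,g,j] * x[b,t,j,c]` — linear in x.
#'
#' @param x Feature array `(B, T, J, C)`.
#' @param alpha Assignment array `(B, G, J)`.
#' @return Group feature array `(B, T, G, C)`.
#' @export
project_to_groups <- function(x, alpha) {
  d <- dim(x)
  G <- dim(alpha)[2]
  if (dim(alpha)[1] != d[1] || dim(alpha)[3] != d[3])
    stop("alpha of shape ", paste(dim(alpha), collapse = "x"),
         " incompatible with features ", paste(d, collapse = "x"))
  out <- projGC(matrix(x, d[1] * d[2] * d[3], d[4]), alpha,
                d[1], d[2], d[3], G)
  array(out, c(d[1], d[2], G, d[4]))
}

#' Redistribute group features back to joints
#'
#' `Z[b,t,j,c] = sum_g z[b,t,g,c] * alpha[b,g,j]`.
#'
#' @param z Group feature array `(B, T, G, C)`.
#' @param alpha Assignment array `(B, G, J)`.
#' @return Joint feature array `(B, T, J, C)`.
#' @export
back_project <- function(z, alpha) {
  d <- dim(z)
  J <- dim(alpha)[3]
  out <- backPC(matrix(z, d[1] * d[2] * d[3], d[4]), alpha,
                d[1], d[2], J, d[3])
  array(out, c(d[1], d[2], J, d[4]))
}

# ---- two-stage grouped attention on the (b,t,g) site matrix ----------------

# One stage: reshape the (B*T*G) x C site matrix into token sequences,
# apply the residual attention layer, reshape back.
#' @keywords internal
att_stage_fwd <- function(xm, B, T, G, stage, params, cfg) {
  C <- ncol(xm)
  p <- if (stage == "temporal") params$att_t else params$att_g
  if (stage == "temporal") {
    arr <- array(xm, c(B, T, G, C))
    tok <- aperm(arr, c(1, 3, 2, 4))           # (B, G, T, C)
    dim(tok) <- c(B * G, T, C)
  } else {
    tok <- xm
    dim(tok) <- c(B * T, G, C)
  }
  r <- att_fwd(tok, p, cfg$n_heads, cfg$scale)
  y <- r$out
  if (stage == "temporal") {
    dim(y) <- c(B, G, T, C)
    y <- aperm(y, c(1, 3, 2, 4))
  }
  dim(y) <- c(B * T * G, C)
  list(out = y, cache = list(att = r$cache, stage = stage))
}

#' @keywords internal
att_stage_bwd <- function(dym, B, T, G, cache, params) {
  C <- ncol(dym)
  stage <- cache$stage
  p <- if (stage == "temporal") params$att_t else params$att_g
  if (stage == "temporal") {
    arr <- array(dym, c(B, T, G, C))
    tok <- aperm(arr, c(1, 3, 2, 4))
    dim(tok) <- c(B * G, T, C)
  } else {
    tok <- dym
    dim(tok) <- c(B * T, G, C)
  }
  r <- att_bwd(tok, cache$att, p)
  dx <- r$dx
  if (stage == "temporal") {
    dim(dx) <- c(B, G, T, C)
    dx <- aperm(dx, c(1, 3, 2, 4))
  }
  dim(dx) <- c(B * T * G, C)
  list(dx = dx, grads = r$grads, stage = stage)
}

#' Two-stage grouped multi-head self-attention
#'
#' Stage `"temporal"` attends over the T' time steps within each (sample,
#' group) sequence; stage `"group"` attends over the G groups at each
#' (sample, time step).  Each stage is one residual multi-head
#' scaled-dot-product self-attention layer with a learned output projection.
#'
#' @param g Group feature array `(B, T, G, C)`.
#' @param params list with attention parameter sets `att_t` and `att_g`.
#' @param cfg A [sadg_config].
#' @return Attended group feature array, same shape as `g`.
#' @export
grouped_attention <- function(g, params, cfg = sadg_config()) {
  d <- dim(g)
  r <- grouped_attention_fwd(matrix(g, d[1] * d[2] * d[3], d[4]),
                             d[1], d[2], d[3], params, cfg)
  array(r$out, d)
}

#' @keywords internal
grouped_attention_fwd <- function(xm, B, T, G, params, cfg) {
  if (ncol(xm) %% cfg$n_heads != 0)
    stop("channels ", ncol(xm), " not divisible by n_heads ", cfg$n_heads)
  caches <- vector("list", 2)
  for (s in 1:2) {
    r <- att_stage_fwd(xm, B, T, G, cfg$stage_order[s], params, cfg)
    xm <- r$out
    caches[[s]] <- r$cache
  }
  list(out = xm, caches = caches)
}

#' @keywords internal
grouped_attention_bwd <- function(dym, B, T, G, fwd, params) {
  grads <- list(att_t = NULL, att_g = NULL)
  for (s in 2:1) {
    r <- att_stage_bwd(dym, B, T, G, fwd$caches[[s]], params)
    dym <- r$dx
    key <- if (r$stage == "temporal") "att_t" else "att_g"
    grads[[key]] <- tree_add(grads[[key]], r$grads)
  }
  list(dx = dym, grads = grads)
}

# ---- full module ------------------------------------------------------------

#' SADG module forward pass
#'
#' Composition: motion amplitude -> group mask -> group projection ->
#' two-stage attention -> back-projection -> output projection -> residual
#' add with the module input.
#'
#' @param x Fused feature array `(B, T, J, C)`.
#' @param params SADG parameter list (`mask`, `att_t`, `att_g`, `out`).
#' @param cfg A [sadg_config].
#' @return list with `out` (same shape as `x`) and `alpha` `(B, G, J)`.
#' @export
sadg_forward <- function(x, params, cfg = sadg_config()) {
  d <- dim(x)
  r <- sadg_fwd_m(matrix(x, d[1] * d[2] * d[3], d[4]), d[1], d[2], d[3],
                  params, cfg)
  list(out = array(r$out, d), alpha = r$cache$alpha)
}

#' @keywords internal
sadg_fwd_m <- function(xm, B, T, J, params, cfg) {
  ts <- timeStdC(xm, B, T, J)
  gm <- group_mask_fwd(ts$M, B, J, params$mask)
  G <- gm$cache$G
  Xg <- projGC(xm, gm$alpha, B, T, J, G)
  ga <- grouped_attention_fwd(Xg, B, T, G, params, cfg)
  Zj <- backPC(ga$out, gm$alpha, B, T, J, G)
  om <- linear_fwd(Zj, params$out)
  list(out = xm + om,
       cache = list(ts = ts, gm = gm$cache, alpha = gm$alpha, ga = ga,
                    Zatt = ga$out, Zj = Zj, G = G))
}

# `xm` is the module's forward input (threaded, not cached).
#' @keywords internal
sadg_bwd_m <- function(dym, xm, B, T, J, cache, params, cfg) {
  G <- cache$G
  ob <- linear_bwd(dym, cache$Zj, params$out)
  grads <- list(out = list(W = ob$W, b = ob$b))
  bp <- backPBwdC(ob$dx, cache$Zatt, cache$alpha, B, T, J, G)
  ab <- grouped_attention_bwd(bp$dz, B, T, G, cache$ga, params)
  grads$att_t <- ab$grads$att_t
  grads$att_g <- ab$grads$att_g
  pb <- projGBwdC(ab$dx, xm, cache$alpha, B, T, J, G)
  mb <- group_mask_bwd(bp$dalpha + pb$dalpha, cache$gm, params$mask)
  grads$mask <- mb$grads
  dx_amp <- timeStdBwdC(mb$dMm, xm, cache$ts$MU, cache$ts$M, B, T, J)
  list(dx = dym + pb$dx + dx_amp, grads = grads)
}
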