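# Independent nested-loop reference implementations used to validate the
# vectorized/compiled paths.  These are deliberately written in the most
# literal way possible (explicit loops over every index) and share no code
# with the package internals.

oracle_motion_amplitude <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1], d[3], d[4]))
  for (b in seq_len(d[1])) for (j in seq_len(d[3])) for (c in seq_len(d[4])) {
    v <- x[b, , j, c]
    mu <- sum(v) / length(v)
    out[b, j, c] <- sqrt(sum((v - mu)^2) / length(v))
  }
  out
}

oracle_project_to_groups <- function(x, alpha) {
  d <- dim(x)
  G <- dim(alpha)[2]
  out <- array(0, c(d[1], d[2], G, d[4]))
  for (b in seq_len(d[1])) for (t in seq_len(d[2])) for (g in seq_len(G))
    for (c in seq_len(d[4])) {
      acc <- 0
      for (j in seq_len(d[3])) acc <- acc + alpha[b, g, j] * x[b, t, j, c]
      out[b, t, g, c] <- acc
    }
  out
}

oracle_back_project <- function(z, alpha) {
  d <- dim(z)
  J <- dim(alpha)[3]
  out <- array(0, c(d[1], d[2], J, d[4]))
  for (b in seq_len(d[1])) for (t in seq_len(d[2])) for (j in seq_len(J))
    for (c in seq_len(d[4])) {
      acc <- 0
      for (g in seq_len(d[3])) acc <- acc + z[b, t, g, c] * alpha[b, g, j]
      out[b, t, j, c] <- acc
    }
  out
}

# One residual multi-head self-attention layer, fully looped.
# x: (N, L, C); params: q/k/v/o each list(W, b); heads are contiguous
# channel blocks of width C/H.
oracle_attention_layer <- function(x, params, H, scale = NULL) {
  d <- dim(x)
  N <- d[1]; L <- d[2]; C <- d[3]
  D <- C / H
  if (is.null(scale)) scale <- 1 / sqrt(D)
  out <- array(0, d)
  lin <- function(v, p) as.vector(t(p$W) %*% v + p$b)
  for (n in seq_len(N)) {
    Q <- matrix(0, L, C); K <- matrix(0, L, C); V <- matrix(0, L, C)
    for (l in seq_len(L)) {
      Q[l, ] <- lin(x[n, l, ], params$q)
      K[l, ] <- lin(x[n, l, ], params$k)
      V[l, ] <- lin(x[n, l, ], params$v)
    }
    Z <- matrix(0, L, C)
    for (h in seq_len(H)) {
      cols <- ((h - 1) * D + 1):(h * D)
      for (i in seq_len(L)) {
        s <- numeric(L)
        for (j in seq_len(L)) s[j] <- sum(Q[i, cols] * K[j, cols]) * scale
        a <- exp(s - max(s)); a <- a / sum(a)
        for (j in seq_len(L)) Z[i, cols] <- Z[i, cols] + a[j] * V[j, cols]
      }
    }
    for (l in seq_len(L))
      out[n, l, ] <- x[n, l, ] + lin(Z[l, ], params$o)
  }
  out
}

# The two-stage grouped attention: temporal tokens per (b, g), then group
# tokens per (b, t), via the looped layer above.
oracle_grouped_attention <- function(g, params, H, scale = NULL,
                                     stage_order = c("temporal", "group")) {
  d <- dim(g)
  B <- d[1]; T <- d[2]; G <- d[3]; C <- d[4]
  x <- g
  for (stage in stage_order) {
    if (stage == "temporal") {
      tok <- array(0, c(B * G, T, C))
      for (b in seq_len(B)) for (gg in seq_len(G))
        tok[(gg - 1) * B + b, , ] <- x[b, , gg, ]
      y <- oracle_attention_layer(tok, params$att_t, H, scale)
      for (b in seq_len(B)) for (gg in seq_len(G))
        x[b, , gg, ] <- y[(gg - 1) * B + b, , ]
    } else {
      tok <- array(0, c(B * T, G, C))
      for (b in seq_len(B)) for (t in seq_len(T))
        tok[(t - 1) * B + b, , ] <- x[b, t, , ]
      y <- oracle_attention_layer(tok, params$att_g, H, scale)
      for (b in seq_len(B)) for (t in seq_len(T))
        x[b, t, , ] <- y[(t - 1) * B + b, , ]
    }
  }
  x
}

oracle_pool <- function(z) {
  d <- dim(z)
  out <- matrix(0, d[1], d[4])
  for (b in seq_len(d[1])) for (c in seq_len(d[4])) {
    acc <- 0
    for (t in seq_len(d[2])) for (j in seq_len(d[3])) acc <- acc + z[b, t, j, c]
    out[b, c] <- acc / (d[2] * d[3])
  }
  out
}

oracle_head <- function(x, params) {
  n <- nrow(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- as.vector(t(params$l1$W) %*% x[i, ] + params$l1$b)
    h[h < 0] <- 0
    out[i] <- sum(params$l2$W[, 1] * h) + params$l2$b
  }
  out
}

oracle_mse <- function(y_hat, y) {
  acc <- 0
  for (i in seq_along(y)) acc <- acc + 0.5 * (y_hat[i] - y[i])^2
  acc / length(y)
}

oracle_mad <- function(y, y_hat) {
  acc <- 0
  for (i in seq_along(y)) acc <- acc + abs(y[i] - y_hat[i])
  acc / length(y)
}

oracle_rmse <- function(y, y_hat) {
  acc <- 0
  for (i in seq_along(y)) acc <- acc + (y[i] - y_hat[i])^2
  sqrt(acc / length(y))
}

oracle_mape <- function(y, y_hat) {
  acc <- 0
  for (i in seq_along(y)) acc <- acc + abs((y[i] - y_hat[i]) / y[i])
  100 * acc / length(y)
}

# rank-then-Pearson with average ranks, written out long-hand
oracle_src <- function(y, y_hat) {
  avg_rank <- function(v) {
    n <- length(v)
    r <- numeric(n)
    for (i in seq_len(n)) r[i] <- sum(v < v[i]) + (1 + sum(v == v[i])) / 2
    r
  }
  q <- avg_rank(y); w <- avg_rank(y_hat)
  qm <- mean(q); wm <- mean(w)
  sum((q - qm) * (w - wm)) / sqrt(sum((q - qm)^2) * sum((w - wm)^2))
}

# minimal-jump angle unwrapping by brute-force search over k in -2..2
oracle_unwrap <- function(x) {
  out <- numeric(length(x))
  out[1] <- x[1]
  for (t in 2:length(x)) {
    best <- NULL; bestd <- Inf
    for (k in -2:2) {
      cand <- x[t] + 360 * k
      if (abs(cand - out[t - 1]) < bestd) {
        bestd <- abs(cand - out[t - 1]); best <- cand
      }
    }
    out[t] <- best
  }
  out
}

# hand-rolled adjusted Rand index from the contingency table
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_ <- ai * bj / n2
  (nij - exp_) / ((ai + bj) / 2 - exp_)
}
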