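# End-to-end differentiability: analytic backpropagation vs central finite
# differences on a tiny but complete model (both streams, SADG, head).

test_that("backpropagated gradients match finite differences", {
  m <- init_model(tiny_model_config(), seed = 1)
  set.seed(2)
  B <- 2; T <- 8; J <- 4
  pos <- rand_tensor(B, T, J, 3)
  ori <- rand_tensor(B, T, J, 4)
  y <- c(0.5, 0.8)

  loss_fn <- function(model) {
    f <- d2sta:::model_fwd(model, pos, ori, training = TRUE)
    mse_loss(f$y, y)
  }
  fw <- d2sta:::model_fwd(m, pos, ori, training = TRUE)
  bw <- d2sta:::model_bwd(m, fw$cache, (fw$y - y) / length(y))

  flatten_paths <- function(tree, prefix = list()) {
    if (is.list(tree)) {
      out <- list()
      keys <- if (is.null(names(tree))) seq_along(tree) else names(tree)
      for (k in keys)
        out <- c(out, flatten_paths(tree[[k]], c(prefix, list(k))))
      return(out)
    }
    list(prefix)
  }
  get_leaf <- function(tree, p) { for (k in p) tree <- tree[[k]]; tree }
  set_leaf <- function(tree, p, v) {
    if (length(p) == 1) { tree[[p[[1]]]] <- v; return(tree) }
    tree[[p[[1]]]] <- set_leaf(tree[[p[[1]]]], p[-1], v)
    tree
  }

  paths <- flatten_paths(m$params)
  h <- 1e-5
  for (rep in 1:30) {
    p <- paths[[sample(length(paths), 1)]]
    leaf <- get_leaf(m$params, p)
    i <- sample(length(leaf), 1)
    g_ana <- get_leaf(bw$grads, p)[i]
    m2 <- m
    leaf[i] <- leaf[i] + h
    m2$params <- set_leaf(m$params, p, leaf)
    lp <- loss_fn(m2)
    leaf[i] <- leaf[i] - 2 * h
    m2$params <- set_leaf(m$params, p, leaf)
    lm <- loss_fn(m2)
    g_num <- (lp - lm) / (2 * h)
    expect_lt(abs(g_ana - g_num) / max(abs(g_ana), abs(g_num), 1e-6), 1e-3,
              label = paste("gradient at", paste(unlist(p), collapse = "/")))
  }

  # gradient w.r.t. the input is finite and nonzero (differentiable through
  # the softmax mask and both attention stages)
  expect_true(all(is.finite(bw$dpos)))
  expect_gt(max(abs(bw$dpos)), 0)
  for (rep in 1:10) {
    i <- sample(length(pos), 1)
    p2 <- pos
    p2[i] <- p2[i] + h
    lp <- mse_loss(d2sta:::model_fwd(m, p2, ori, training = TRUE)$y, y)
    p2[i] <- p2[i] - 2 * h
    lm <- mse_loss(d2sta:::model_fwd(m, p2, ori, training = TRUE)$y, y)
    g_num <- (lp - lm) / (2 * h)
    expect_lt(abs(bw$dpos[i] - g_num) / max(abs(g_num), abs(bw$dpos[i]), 1e-6),
              1e-3)
  }
})
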