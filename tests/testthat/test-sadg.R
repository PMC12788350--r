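# SADG: motion amplitude, soft grouping, two-stage attention,
# back-projection, residual composition.

test_that("motion amplitude is the population std over time", {
  # time-constant input -> exactly zero
  x <- array(3, c(2, 5, 3, 4))
  expect_true(all(motion_amplitude(x) == 0))

  # alternating +-1 over two frames -> amplitude exactly 1
  x2 <- array(0, c(1, 2, 1, 1))
  x2[1, , 1, 1] <- c(1, -1)
  expect_equal(as.vector(motion_amplitude(x2)), 1)

  # random tensors match the naive loop oracle
  set.seed(1)
  for (i in 1:20) {
    x3 <- rand_tensor(2, sample(2:6, 1), 3, 4)
    expect_equal(motion_amplitude(x3), oracle_motion_amplitude(x3),
                 tolerance = 1e-6)
  }

  # invariant to temporal permutation
  x4 <- rand_tensor(2, 7, 3, 4)
  expect_equal(motion_amplitude(x4),
               motion_amplitude(x4[, sample(7), , , drop = FALSE]),
               tolerance = 1e-12)
})

test_that("the group mask is a proper softmax over groups", {
  C <- 6; d <- 4; G <- 3
  zero <- list(l1 = list(W = matrix(0, C, d), b = numeric(d)),
               l2 = list(W = matrix(0, d, G), b = numeric(G)))
  m <- rand_tensor(2, 5, C)
  a0 <- group_mask(abs(m), zero)
  expect_equal(dim(a0), c(2, G, 5))
  expect_true(all(abs(a0 - 1 / G) < 1e-12))     # zero logits -> uniform

  set.seed(2)
  p <- list(l1 = init_linear_test(C, d), l2 = init_linear_test(d, G))
  a <- group_mask(abs(m), p)
  expect_true(all(abs(apply(a, c(1, 3), sum) - 1) < 1e-6))
  expect_true(all(a > 0 & a < 1))

  # shift invariance: adding a constant to all logits of a joint
  p2 <- p
  p2$l2$b <- p2$l2$b + 5
  expect_equal(group_mask(abs(m), p2), a, tolerance = 1e-9)

  # a dominating logit saturates its group
  p3 <- zero
  p3$l2$b <- c(20, 0, 0)
  a3 <- group_mask(abs(m), p3)
  expect_true(all(a3[, 1, ] > 0.9999))
})

test_that("group projection and back-projection match loop oracles", {
  set.seed(3)
  for (i in 1:20) {
    B <- 2; T <- sample(2:4, 1); J <- sample(3:6, 1); G <- 3; C <- 4
    x <- rand_tensor(B, T, J, C)
    aljg <- matrix(rexp(B * J * G), B * J, G)
    aljg <- aljg / rowSums(aljg)
    alpha <- aperm(array(aljg, c(B, J, G)), c(1, 3, 2))
    Xg <- project_to_groups(x, alpha)
    expect_equal(Xg, oracle_project_to_groups(x, alpha), tolerance = 1e-6)
    z <- rand_tensor(B, T, G, C)
    expect_equal(back_project(z, alpha), oracle_back_project(z, alpha),
                 tolerance = 1e-6)
  }
})

test_that("selector and uniform masks route features as expected", {
  B <- 1; T <- 3; J <- 4; G <- 2; C <- 5
  set.seed(4)
  x <- rand_tensor(B, T, J, C)
  # one-hot: group 1 = joint 3 alone
  alpha <- array(0, c(B, G, J))
  alpha[1, 1, 3] <- 1
  alpha[1, 2, 1] <- 1
  Xg <- project_to_groups(x, alpha)
  expect_equal(Xg[1, , 1, ], x[1, , 3, ])
  # uniform mask: every group averages all joints identically
  au <- array(1 / G, c(B, G, J))
  Xu <- project_to_groups(x, au)
  expect_equal(Xu[1, , 1, ], Xu[1, , 2, ])
  expect_equal(Xu[1, , 1, ], apply(x[1, , , ], c(1, 3), sum) / G)

  # back-projection with a one-hot mask routes group 2 to joint 5 alone
  J2 <- 5
  z <- rand_tensor(B, T, G, C)
  a2 <- array(0, c(B, G, J2))
  a2[1, 2, 5] <- 1
  Zj <- back_project(z, a2)
  expect_equal(Zj[1, , 5, ], z[1, , 2, ])
  expect_true(all(Zj[1, , 1:4, ] == 0))
})

test_that("grouped attention matches a fully looped reference", {
  set.seed(5)
  for (i in 1:20) {
    B <- 2; T <- sample(2:4, 1); G <- 3; C <- 8; H <- 2
    g <- rand_tensor(B, T, G, C)
    params <- list(att_t = rand_attention_params(C),
                   att_g = rand_attention_params(C))
    cfg <- sadg_config(n_groups = G, n_heads = H)
    got <- grouped_attention(g, params, cfg)
    want <- oracle_grouped_attention(g, params, H)
    expect_equal(got, want, tolerance = 1e-5)
  }
  # configurable stage order changes the result accordingly
  set.seed(6)
  g <- rand_tensor(2, 3, 3, 8)
  params <- list(att_t = rand_attention_params(8),
                 att_g = rand_attention_params(8))
  rev_cfg <- sadg_config(n_groups = 3, n_heads = 2,
                         stage_order = c("group", "temporal"))
  expect_equal(grouped_attention(g, params, rev_cfg),
               oracle_grouped_attention(g, params, 2,
                                        stage_order = c("group", "temporal")),
               tolerance = 1e-5)
  expect_error(grouped_attention(g, params, sadg_config(n_heads = 3)),
               "divisible")
})

test_that("attention degenerate cases: single token and identical tokens", {
  set.seed(7)
  C <- 6; H <- 2
  p <- rand_attention_params(C)
  # single token: softmax weight is exactly 1 -> out = x + o(v(x))
  x1 <- rand_tensor(3, 1, C)
  r1 <- d2sta:::att_fwd(x1, p, H)
  xm <- matrix(x1, 3, C)
  vm <- xm %*% p$v$W + matrix(p$v$b, 3, C, byrow = TRUE)
  om <- vm %*% p$o$W + matrix(p$o$b, 3, C, byrow = TRUE)
  expect_equal(matrix(r1$out, 3, C), xm + om, tolerance = 1e-10)

  # identical tokens: every attention row is uniform
  x2 <- array(rep(rnorm(C), each = 4 * 5), c(4, 5, C))
  r2 <- d2sta:::att_fwd(x2, p, H)
  expect_true(all(abs(r2$cache$A - 1 / 5) < 1e-12))
})

test_that("attention rows and mask columns always normalise to 1", {
  set.seed(8)
  m <- init_model(tiny_model_config(), seed = 9)
  for (i in 1:5) {
    pos <- rand_tensor(2, 12, 5, 3)
    ori <- rand_tensor(2, 12, 5, 4)
    r <- d2sta:::model_fwd(m, pos, ori, training = TRUE)
    a <- r$cache$alpha
    expect_true(all(abs(apply(a, c(1, 3), sum) - 1) < 1e-6))
    for (st in r$cache$sadg$ga$caches) {
      A <- st$att$A
      L <- ncol(A)
      expect_true(all(abs(rowSums(matrix(A, ncol = L)) - 1) < 1e-6))
    }
  }
})

test_that("sadg_forward is the identity when its output projection is zero", {
  set.seed(10)
  cfg <- sadg_config(n_groups = 3, n_heads = 2, mask_hidden = 4)
  p <- d2sta:::init_sadg(8L, cfg)
  x <- rand_tensor(2, 4, 5, 8)
  p0 <- p
  p0$out$W[] <- 0; p0$out$b[] <- 0
  r <- sadg_forward(x, p0, cfg)
  expect_equal(r$out, x, tolerance = 1e-12)

  # shape contract and mask normalisation for random parameters
  r2 <- sadg_forward(x, p, cfg)
  expect_equal(dim(r2$out), dim(x))
  expect_equal(dim(r2$alpha), c(2, 3, 5))
  expect_true(all(abs(apply(r2$alpha, c(1, 3), sum) - 1) < 1e-6))
})

test_that("projection maps are linear in their feature argument", {
  set.seed(11)
  x <- rand_tensor(2, 3, 4, 5)
  alpha <- group_mask(motion_amplitude(x),
                      list(l1 = init_linear_test(5, 4),
                           l2 = init_linear_test(4, 2)))
  expect_equal(project_to_groups(3.5 * x, alpha),
               3.5 * project_to_groups(x, alpha), tolerance = 1e-12)
  z <- rand_tensor(2, 3, 2, 5)
  expect_equal(back_project(-2 * z, alpha), -2 * back_project(z, alpha),
               tolerance = 1e-12)
})
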