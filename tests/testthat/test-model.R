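# Pooling, regression head, loss and the assembled network.

test_that("spatio-temporal pooling is the mean over time and joints", {
  z <- array(2.5, c(3, 4, 5, 2))
  expect_true(all(pool_spatiotemporal(z) == 2.5))   # mean of a constant

  z1 <- array(0, c(1, 4, 5, 1))
  z1[1, 2, 3, 1] <- 7
  expect_equal(pool_spatiotemporal(z1)[1, 1], 7 / 20)  # single mass

  set.seed(1)
  for (i in 1:20) {
    z2 <- rand_tensor(2, sample(2:5, 1), 3, 4)
    expect_equal(pool_spatiotemporal(z2), oracle_pool(z2), tolerance = 1e-7)
  }
})

test_that("the regression head is two linear layers with a ReLU", {
  # all-zero weights, b2 = 0.7 -> constant output
  p <- list(l1 = list(W = matrix(0, 6, 4), b = numeric(4)),
            l2 = list(W = matrix(0, 4, 1), b = 0.7))
  x <- matrix(rnorm(12), 2, 6)
  expect_equal(regression_head(x, p), c(0.7, 0.7))

  # negative hidden biases kill the hidden layer through the ReLU
  p2 <- p
  p2$l1$b[] <- -1
  p2$l2$W[] <- rnorm(4)
  expect_equal(regression_head(x, p2), c(0.7, 0.7))

  set.seed(2)
  for (i in 1:20) {
    p3 <- list(l1 = init_linear_test(6, 4), l2 = init_linear_test(4, 1))
    x3 <- matrix(rnorm(18), 3, 6)
    expect_equal(regression_head(x3, p3), oracle_head(x3, p3),
                 tolerance = 1e-6)
  }
  expect_error(regression_head(matrix(0, 2, 5), p), "channels")
})

test_that("the loss is half mean squared error", {
  expect_equal(mse_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(mse_loss(2, 0), 2)               # 0.5 * 4
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(32); b <- rnorm(32)
    expect_equal(mse_loss(a, b), oracle_mse(a, b), tolerance = 1e-9)
    expect_gte(mse_loss(a, b), 0)
  }
  expect_error(mse_loss(1:3, 1:4), "length mismatch")
})

test_that("the default full-width model has the documented geometry", {
  m <- init_model(model_config(), seed = 1)
  expect_equal(m$config$fused_channels, 512L)
  expect_equal(m$config$head_hidden, 128L)
  expect_equal(m$config$head_hidden / m$config$fused_channels, 0.25)
  expect_equal(nrow(m$params$head$l1$W), 512L)
  expect_equal(dim(m$params$head$l2$W), c(128L, 1L))
})

test_that("a full forward pass on (B=2, T=100, J=25) yields finite scalars", {
  m <- init_model(tiny_model_config(), seed = 4)
  set.seed(5)
  r <- d2sta:::model_fwd(m, rand_tensor(2, 100, 25, 3),
                         rand_tensor(2, 100, 25, 4), training = TRUE)
  expect_length(r$y, 2)
  expect_true(all(is.finite(r$y)))
  # fused temporal length honours the T/4 contract
  expect_equal(unname(r$cache$geom["T"]), 25)
})

test_that("unit-interval score scaling round-trips by a factor of 100", {
  y_raw <- c(37.5, 80, 99.2)
  y_unit <- y_raw / 100
  expect_equal(y_unit * 100, y_raw, tolerance = 1e-12)
  expect_equal(mad_score(y_raw, y_raw * 0.9),
               100 * mad_score(y_unit, y_unit * 0.9), tolerance = 1e-12)
})
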