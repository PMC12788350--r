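# Dual-stream STGCN backbone: temporal-length contract, null propagation,
# joint equivariance, stream independence.

test_that("temporal length follows the k=3, p=1 convolution formula", {
  set.seed(1)
  for (stride in c(1L, 2L)) {
    blk <- d2sta:::init_block(3L, 6L, stride, batchnorm = TRUE)
    x <- rand_tensor(2, 10, 4, 3)
    r <- stgcn_block(x, blk$params, blk$state, stride, training = TRUE)
    expect_equal(dim(r$out), c(2, (10 + 2 - 3) %/% stride + 1, 4, 6))
  }
  # full stack: strides (1, 2, 2) on T = 100 gives exactly T/4 = 25
  m <- init_model(tiny_model_config(), seed = 2)
  f <- dual_stream_forward(rand_tensor(1, 100, 5, 3),
                           rand_tensor(1, 100, 5, 4), m)
  expect_equal(dim(f$out)[2], 25)
})

test_that("zero input with zero offsets propagates to zero output", {
  set.seed(3)
  # batch-norm blocks carry no convolution offsets and beta starts at zero
  blk <- d2sta:::init_block(3L, 6L, 1L, batchnorm = TRUE)
  x <- array(0, c(2, 8, 4, 3))
  r <- stgcn_block(x, blk$params, blk$state, 1L, training = TRUE)
  expect_true(all(r$out == 0))

  # without batch norm the offsets exist; zeroing them restores the property
  blk2 <- d2sta:::init_block(3L, 6L, 1L, batchnorm = FALSE)
  blk2$params$sp$b[] <- 0
  blk2$params$tc$b[] <- 0
  blk2$params$res$b[] <- 0
  r2 <- stgcn_block(x, blk2$params, blk2$state, 1L, training = TRUE)
  expect_true(all(r2$out == 0))
})

test_that("the spatial 1x1 stage is joint-permutation equivariant", {
  set.seed(4)
  blk <- d2sta:::init_block(3L, 5L, 1L, batchnorm = TRUE)
  x <- rand_tensor(2, 9, 6, 3)
  perm <- sample(6)
  r1 <- stgcn_block(x, blk$params, blk$state, 1L, training = TRUE)
  r2 <- stgcn_block(x[, , perm, , drop = FALSE], blk$params, blk$state, 1L,
                    training = TRUE)
  expect_equal(r2$out, r1$out[, , perm, , drop = FALSE], tolerance = 1e-10)
})

test_that("streams are independent until channel concatenation", {
  set.seed(5)
  m <- init_model(tiny_model_config(), seed = 6)
  pos <- rand_tensor(2, 16, 5, 3)
  ori1 <- rand_tensor(2, 16, 5, 4)
  ori2 <- array(0, c(2, 16, 5, 4))
  f1 <- dual_stream_forward(pos, ori1, m)
  f2 <- dual_stream_forward(pos, ori2, m)
  cp <- f1$c_pos
  C <- dim(f1$out)[4]
  expect_equal(cp, C / 2)
  # zeroing orientations changes only the orientation half of the channels
  expect_equal(f1$out[, , , 1:cp], f2$out[, , , 1:cp])
  expect_false(isTRUE(all.equal(f1$out[, , , (cp + 1):C],
                                f2$out[, , , (cp + 1):C])))
  # shape mismatch across streams errors
  expect_error(dual_stream_forward(pos, rand_tensor(2, 15, 5, 4), m),
               "disagree")
})

test_that("single-modality ablations feed one stream's input to both branches", {
  set.seed(7)
  cfg <- tiny_model_config(ablation = "orientation_only")
  m <- init_model(cfg, seed = 8)
  expect_equal(m$config$pos_stream$in_channels, 4L)  # quaternion width
  ori <- rand_tensor(2, 12, 5, 4)
  r <- d2sta:::model_fwd(m, rand_tensor(2, 12, 5, 3), ori)
  expect_length(r$y, 2)
  expect_true(all(is.finite(r$y)))
})

test_that("non-finite input is rejected", {
  set.seed(9)
  blk <- d2sta:::init_block(3L, 4L, 1L, batchnorm = TRUE)
  x <- rand_tensor(1, 6, 3, 3)
  x[1, 2, 1, 1] <- NaN
  expect_error(stgcn_block(x, blk$params, blk$state, 1L), "non-finite")
})
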