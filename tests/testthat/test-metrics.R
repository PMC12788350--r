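# Evaluation metrics and their identities.

test_that("metric values match hand examples and loop oracles", {
  expect_equal(mad_score(c(1, 2), c(1, 2)), 0)
  expect_equal(mad_score(c(0, 1), c(1, 0)), 1)
  expect_equal(rmse_score(c(0, 0), c(3, 4)), sqrt(25 / 2))
  expect_equal(mape_score(100, 99), 1)
  expect_equal(mape_score(c(50, 50), c(50, 50)), 0)
  set.seed(1)
  for (i in 1:20) {
    y <- runif(100, 10, 100); yh <- y + rnorm(100)
    expect_equal(mad_score(y, yh), oracle_mad(y, yh), tolerance = 1e-12)
    expect_equal(rmse_score(y, yh), oracle_rmse(y, yh), tolerance = 1e-12)
    expect_equal(mape_score(y, yh), oracle_mape(y, yh), tolerance = 1e-12)
    expect_equal(src_score(y, yh), oracle_src(y, yh), tolerance = 1e-12)
  }
})

test_that("error conditions are explicit", {
  expect_error(mad_score(numeric(0), numeric(0)), "empty")
  expect_error(mape_score(c(1, 0), c(1, 1)), "zero")
  expect_error(src_score(1, 1), "at least 2")
  expect_warning(expect_true(is.nan(src_score(c(1, 1, 1), c(1, 2, 3)))),
                 "undefined")
})

test_that("rank correlation handles monotone maps and ties", {
  y <- c(3, 1, 4, 1.5, 9)
  expect_equal(src_score(y, exp(y)), 1)         # strictly increasing map
  expect_equal(src_score(y, -y^3), -1)          # strictly decreasing map
  # ties via average ranks, against the rank-then-Pearson oracle
  y2 <- c(1, 2, 2, 3); yh2 <- c(1, 3, 2, 4)
  expect_equal(src_score(y2, yh2), oracle_src(y2, yh2), tolerance = 1e-12)
  expect_equal(src_score(y2, yh2),
               suppressWarnings(cor(y2, yh2, method = "spearman")),
               tolerance = 1e-12)
})

test_that("metric identities hold on random inputs", {
  set.seed(2)
  for (i in 1:20) {
    y <- runif(50, 1, 100); yh <- y + rnorm(50, sd = 5)
    expect_lte(mad_score(y, yh), rmse_score(y, yh))   # Jensen
    p <- sample(50)                                   # joint permutation
    expect_equal(mad_score(y[p], yh[p]), mad_score(y, yh))
    expect_equal(src_score(y[p], yh[p]), src_score(y, yh),
                 tolerance = 1e-12)
    # scaling: mad/rmse linear, mape invariant
    expect_equal(mad_score(3 * y, 3 * yh), 3 * mad_score(y, yh))
    expect_equal(rmse_score(3 * y, 3 * yh), 3 * rmse_score(y, yh))
    expect_equal(mape_score(3 * y, 3 * yh), mape_score(y, yh),
                 tolerance = 1e-12)
    # src invariant under strictly monotone transforms of either argument
    expect_equal(src_score(exp(y / 50), yh), src_score(y, yh),
                 tolerance = 1e-12)
  }
})

test_that("metrics_report collects all four metrics", {
  set.seed(3)
  y <- runif(20, 10, 90); yh <- y + rnorm(20)
  r <- metrics_report(y, yh)
  expect_s3_class(r, "metrics_report")
  expect_equal(r$n, 20)
  expect_equal(r$mad, mad_score(y, yh))
  expect_equal(r$src, src_score(y, yh))
  expect_output(print(r), "MAD")
})
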