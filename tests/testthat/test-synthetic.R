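# Synthetic generator: planted group structure and the documented score
# function.

test_that("perfect executions score exactly 100 and generation is deterministic", {
  cfg <- synth_config(n_samples = 4, T = 20, J = 8, n_groups_true = 3,
                      amplitude_jitter_sd = 0, noise_sd = 0, seed = 9)
  ds <- generate_synth(cfg)
  expect_true(all(ds$true_params$score == 100))

  ds2 <- generate_synth(cfg)
  expect_identical(ds$samples, ds2$samples)     # bitwise determinism
  expect_identical(ds$true_params, ds2$true_params)
})

test_that("the score function follows the documented formula", {
  # score = clip(100 * (1 - w_amp|s-1| - w_noise*sigma), 0, 100)
  expect_equal(synth_score(1.2, 0, c(1, 2)), 80)
  expect_equal(synth_score(0.9, 0.05, c(1, 2)), 80)
  expect_equal(synth_score(1, 0, c(1, 2)), 100)
  expect_equal(synth_score(3, 0.5, c(1, 2)), 0)  # clipped at 0
  # monotone: non-increasing in |s - 1| and in sigma
  s_grid <- seq(1, 1.5, 0.05)
  sc <- synth_score(s_grid, 0.02)
  expect_true(all(diff(sc) <= 0))
  sig_grid <- seq(0, 0.3, 0.02)
  sc2 <- synth_score(1.1, sig_grid)
  expect_true(all(diff(sc2) <= 0))
})

test_that("joints within a planted group are perfectly correlated on noiseless data", {
  ds <- generate_synth(synth_config(n_samples = 1, T = 40, J = 10,
                                    n_groups_true = 3,
                                    amplitude_jitter_sd = 0, noise_sd = 0,
                                    seed = 2))
  s <- ds$samples[[1]]
  # correlation of displacement magnitude trajectories
  traj <- sapply(1:10, function(j) {
    d <- s$positions[, j, ] - matrix(s$positions[1, j, ], 40, 3, byrow = TRUE)
    d %*% rnorm(3)                              # random projection
  })
  set.seed(1)
  cc <- abs(suppressWarnings(cor(traj)))
  g <- ds$true_groups
  for (a in 1:9) for (b in (a + 1):10) {
    if (g[a] == g[b]) expect_gt(cc[a, b], 0.999)
  }
})

test_that("generated quaternions are unit norm with w >= 0", {
  ds <- generate_synth(synth_config(n_samples = 2, T = 15, J = 6,
                                    n_groups_true = 2, seed = 3))
  for (s in ds$samples) {
    norms <- sqrt(apply(s$orientations^2, c(1, 2), sum))
    expect_true(all(abs(norms - 1) < 1e-9))
    expect_true(all(s$orientations[, , 1] >= 0))
  }
})

test_that("grouping agreement is the adjusted Rand index", {
  truth <- rep(1:3, each = 4)
  expect_equal(grouping_agreement(truth, truth), 1)
  # label permutation leaves agreement at 1
  perm <- c(3, 1, 2)[truth]
  expect_equal(grouping_agreement(perm, truth), 1)
  expect_error(grouping_agreement(1:5, 1:6), "length")

  # agrees with a hand-rolled contingency-table ARI
  set.seed(8)
  for (i in 1:10) {
    a <- sample(1:4, 20, replace = TRUE)
    b <- sample(1:3, 20, replace = TRUE)
    expect_equal(grouping_agreement(a, b), oracle_ari(a, b),
                 tolerance = 1e-12)
  }

  # Monte-Carlo null: random partitions score ~0 on average
  set.seed(9)
  truth2 <- rep(1:2, each = 10)
  null_vals <- replicate(1000, grouping_agreement(
    sample(1:2, 20, replace = TRUE), truth2))
  expect_lt(abs(mean(null_vals)), 0.05)
})

test_that("written datasets round-trip through the file loader", {
  ds <- generate_synth(synth_config(n_samples = 3, T = 12, J = 5,
                                    n_groups_true = 2, seed = 4))
  dir <- withr::local_tempdir()
  path <- write_synth_dataset(ds, dir)
  man <- load_manifest(path)
  expect_equal(man$joint_names, ds$joint_names)
  samples <- load_samples(man, target_len = NULL)
  for (id in names(ds$samples)) {
    expect_equal(samples[[id]]$positions, ds$samples[[id]]$positions,
                 tolerance = 1e-9)
    expect_equal(samples[[id]]$orientations, ds$samples[[id]]$orientations,
                 tolerance = 1e-6)
    expect_equal(samples[[id]]$score, ds$samples[[id]]$score,
                 tolerance = 1e-9)
  }
})
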