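# Shared fixture builders.  Everything is generated in code at test time;
# sizes are kept tiny so oracle loops stay fast.

rand_tensor <- function(..., sd = 1) {
  d <- c(...)
  array(stats::rnorm(prod(d), sd = sd), d)
}

tiny_model_config <- function(...) {
  model_config(channels = c(4, 4, 8), n_groups = 3, n_heads = 2,
               mask_hidden = 5, head_hidden = 4, ...)
}

# Attention parameters for channel count C (seeded by the caller).
rand_attention_params <- function(C) {
  list(q = init_linear_test(C), k = init_linear_test(C),
       v = init_linear_test(C), o = init_linear_test(C))
}

init_linear_test <- function(C, Cout = C) {
  list(W = matrix(stats::rnorm(C * Cout, sd = 0.3), C, Cout),
       b = stats::rnorm(Cout, sd = 0.1))
}

# Writes a tiny valid on-disk dataset (plain-text tables + manifest) and
# returns the manifest path.
write_tiny_dataset <- function(dir, n = 3, T = 12, J = 4, sep = " ",
                               scores = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(scores)) scores <- seq(40, 90, length.out = n)
  rows <- lapply(seq_len(n), function(i) {
    pm <- matrix(round(stats::rnorm(T * J * 3), 4), T, J * 3)
    qm <- matrix(stats::rnorm(T * J * 4), T, J * 4)
    # make quaternion-ish columns non-degenerate
    pp <- sprintf("s%02d_pos.txt", i)
    op <- sprintf("s%02d_ori.txt", i)
    write.table(pm, file.path(dir, pp), row.names = FALSE,
                col.names = FALSE, sep = sep)
    write.table(qm, file.path(dir, op), row.names = FALSE,
                col.names = FALSE, sep = sep)
    data.frame(sample_id = sprintf("s%02d", i), position_path = pp,
               orientation_path = op, exercise_id = "ex1",
               score = scores[i])
  })
  man <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  write.csv(man, path, row.names = FALSE)
  path
}

expect_tree_equal <- function(a, b, tol = 1e-12) {
  fa <- unlist(a); fb <- unlist(b)
  expect_equal(fa, fb, tolerance = tol, ignore_attr = TRUE)
}
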