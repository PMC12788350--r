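# Synthetic skeleton datasets with planted functional-group structure and a
# known, documented score function, so every downstream stage (loading,
# training, grouping recovery) is testable without any external download.
#
# Each of the G groups oscillates coherently: every joint j in group g moves
# along a fixed unit direction u_g as
#   pos(j, t) = rest(j) + s_i * A * sin(2*pi*f_g*t/T + phi_g) * u_g + eps,
# with per-sample amplitude scale s_i = 1 + jitter, eps ~ N(0, sigma_i^2)
# i.i.d. per coordinate.  Orientations are unit quaternions for a rotation
# about u_g with angle proportional to the same sinusoid (angle noise is
# added before quaternionisation, so quaternions stay exactly unit norm).
# The quality score is the documented monotone function
#   score_i = clip(100 * (1 - w_amp*|s_i - 1| - w_noise*sigma_i), 0, 100).

#' Kinect-v2-style joint names (25 joints)
#' @keywords internal
kinect25_joint_names <- function() c(
  "Spine_Base", "Spine_Mid", "Neck", "Head",
  "Shoulder_L", "Elbow_L", "Wrist_L", "Hand_L",
  "Shoulder_R", "Elbow_R", "Wrist_R", "Hand_R",
  "Hip_L", "Knee_L", "Ankle_L", "Foot_L",
  "Hip_R", "Knee_R", "Ankle_R", "Foot_R",
  "Spine_Shoulder", "Tip_L", "Thumb_L", "Tip_R", "Thumb_R")

# A fixed, anatomically plausible rest pose (metres); tests never depend on
# the actual values.
#' @keywords internal
rest_pose25 <- function() {
  m <- rbind(
    c(0, 0, 0.9), c(0, 0, 1.15), c(0, 0, 1.45), c(0, 0, 1.6),
    c(-0.2, 0, 1.4), c(-0.3, 0, 1.15), c(-0.35, 0, 0.9), c(-0.37, 0, 0.82),
    c(0.2, 0, 1.4), c(0.3, 0, 1.15), c(0.35, 0, 0.9), c(0.37, 0, 0.82),
    c(-0.1, 0, 0.85), c(-0.12, 0, 0.45), c(-0.13, 0, 0.08),
    c(-0.13, 0.12, 0.02),
    c(0.1, 0, 0.85), c(0.12, 0, 0.45), c(0.13, 0, 0.08),
    c(0.13, 0.12, 0.02),
    c(0, 0, 1.38), c(-0.38, 0, 0.74), c(-0.34, 0.05, 0.8),
    c(0.38, 0, 0.74), c(0.34, 0.05, 0.8))
  rownames(m) <- kinect25_joint_names()
  m
}

#' Synthetic dataset configuration
#'
#' @param n_samples Number of exercise repetitions to generate.
#' @param T Clip length in frames.
#' @param J Number of joints.
#' @param n_groups_true Number of planted functional groups.
#' @param frequencies Per-group oscillation frequencies in cycles per clip;
#'   must be distinct.
#' @param template_amplitude Oscillation amplitude A of a perfect execution.
#' @param amplitude_jitter_sd SD of the per-sample amplitude scale jitter.
#' @param noise_sd Upper bound of the per-sample coordinate noise level
#'   sigma_i (drawn uniformly from \[0, noise_sd\]).
#' @param score_weights `c(w_amp, w_noise)` of the score function.
#' @param frame_rate_hz Metadata only.
#' @param seed Integer RNG seed; generation is fully deterministic given it.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_samples = 300L, T = 100L, J = 25L,
                         n_groups_true = 6L, frequencies = NULL,
                         template_amplitude = 0.3,
                         amplitude_jitter_sd = 0.15, noise_sd = 0.15,
                         score_weights = c(w_amp = 1, w_noise = 2),
                         frame_rate_hz = 30, seed = 1L) {
  if (is.null(frequencies)) frequencies <- seq_len(n_groups_true)
  stopifnot(n_groups_true <= J, length(frequencies) == n_groups_true,
            !anyDuplicated(frequencies),
            amplitude_jitter_sd >= 0, noise_sd >= 0)
  structure(list(n_samples = as.integer(n_samples), T = as.integer(T),
                 J = as.integer(J), n_groups_true = as.integer(n_groups_true),
                 frequencies = frequencies,
                 template_amplitude = template_amplitude,
                 amplitude_jitter_sd = amplitude_jitter_sd,
                 noise_sd = noise_sd, score_weights = score_weights,
                 frame_rate_hz = frame_rate_hz, seed = as.integer(seed)),
            class = "synth_config")
}

#' The documented synthetic score function
#'
#' @param amplitude_scale Per-sample amplitude scale s.
#' @param noise_level Per-sample noise level sigma.
#' @param weights `c(w_amp, w_noise)`.
#' @return Score in \[0, 100\].
#' @export
synth_score <- function(amplitude_scale, noise_level,
                        weights = c(w_amp = 1, w_noise = 2)) {
  raw <- 100 * (1 - weights[[1]] * abs(amplitude_scale - 1) -
                  weights[[2]] * noise_level)
  pmin(pmax(raw, 0), 100)
}

#' Generate a synthetic skeleton dataset
#'
#' @param config A [synth_config()].
#' @return list of class `synth_dataset` with `samples` (list of
#'   `skeleton_sample`), `true_groups` (J integer labels), `true_params`
#'   (data.frame with per-sample amplitude_scale, noise_level, score),
#'   `joint_names` and the `config`.
#' @export
generate_synth <- function(config = synth_config()) {
  set.seed(config$seed)
  J <- config$J; Tn <- config$T; G <- config$n_groups_true
  joint_names <- if (J == 25L) kinect25_joint_names()
                 else paste0("joint_", seq_len(J))
  rest <- if (J == 25L) rest_pose25()
          else matrix(stats::rnorm(J * 3, sd = 0.3), J, 3)
  # contiguous blocks of joints per group
  true_groups <- sort(rep_len(seq_len(G), J))
  # fixed per-group unit directions and phases (deterministic, not sampled)
  ang <- 2 * pi * (seq_len(G) - 1) / G
  u <- cbind(cos(ang), sin(ang), cos(2 * ang + 1))
  u <- u / sqrt(rowSums(u^2))
  phi <- 2 * pi * (seq_len(G) - 1) / G
  tgrid <- seq_len(Tn)
  w <- config$score_weights
  samples <- vector("list", config$n_samples)
  amp_scale <- numeric(config$n_samples)
  noise_lvl <- numeric(config$n_samples)
  for (i in seq_len(config$n_samples)) {
    s_i <- 1 + stats::rnorm(1, 0, config$amplitude_jitter_sd)
    sigma_i <- stats::runif(1, 0, config$noise_sd)
    amp_scale[i] <- s_i; noise_lvl[i] <- sigma_i
    pos <- array(0, c(Tn, J, 3))
    ori <- array(0, c(Tn, J, 4))
    for (j in seq_len(J)) {
      g <- true_groups[j]
      wave <- sin(2 * pi * config$frequencies[g] * tgrid / Tn + phi[g])
      amp <- s_i * config$template_amplitude * wave
      pos[, j, ] <- rep(rest[j, ], each = Tn) + outer(amp, u[g, ]) +
        stats::rnorm(Tn * 3, 0, sigma_i)
      theta <- 0.5 * s_i * wave + stats::rnorm(Tn, 0, sigma_i)
      ori[, j, ] <- cbind(cos(theta / 2), outer(sin(theta / 2), u[g, ]))
    }
    # enforce non-negative scalar part (double-cover convention)
    flip <- ori[, , 1] < 0
    if (any(flip)) {
      om <- matrix(ori, Tn * J, 4)
      fl <- as.vector(flip)
      om[fl, ] <- -om[fl, ]
      ori <- array(om, c(Tn, J, 4))
    }
    samples[[i]] <- structure(list(
      sample_id = sprintf("synth_%04d", i), exercise_id = "synth_ex1",
      positions = pos, orientations = ori,
      score = as.numeric(synth_score(s_i, sigma_i, w)),
      orientation_kind = "quaternion",
      frame_rate_hz = config$frame_rate_hz), class = "skeleton_sample")
  }
  names(samples) <- vapply(samples, `[[`, "", "sample_id")
  structure(list(samples = samples, true_groups = true_groups,
                 true_params = data.frame(
                   sample_id = names(samples),
                   amplitude_scale = amp_scale, noise_level = noise_lvl,
                   score = vapply(samples, `[[`, 0, "score")),
                 joint_names = joint_names, config = config),
            class = "synth_dataset")
}

#' Write a synthetic dataset to disk in manifest layout
#'
#' Produces `manifest.csv`, a `manifest.joints.txt` sidecar and one
#' whitespace-delimited position/orientation table per sample, so the full
#' file-based pipeline can run end-to-end on synthetic data.
#'
#' @param dataset A `synth_dataset`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_synth_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(dataset$samples, function(s) {
    pp <- paste0(s$sample_id, "_pos.txt")
    op <- paste0(s$sample_id, "_ori.txt")
    dp <- dim(s$positions)
    utils::write.table(matrix(aperm(s$positions, c(3, 2, 1)), dp[2] * dp[3],
                              dp[1]) |> t(),
                       file.path(dir, pp), row.names = FALSE,
                       col.names = FALSE)
    do_ <- dim(s$orientations)
    utils::write.table(matrix(aperm(s$orientations, c(3, 2, 1)),
                              do_[2] * do_[3], do_[1]) |> t(),
                       file.path(dir, op), row.names = FALSE,
                       col.names = FALSE)
    data.frame(sample_id = s$sample_id, position_path = pp,
               orientation_path = op, exercise_id = s$exercise_id,
               score = s$score)
  })
  man <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE)
  writeLines(dataset$joint_names, file.path(dir, "manifest.joints.txt"))
  invisible(path)
}

#' Agreement between a predicted and a planted joint partition
#'
#' Adjusted Rand index between two label vectors over the J joints; 1 for
#' identical partitions (up to label permutation), ~0 for random ones.
#'
#' @param predicted,truth Integer label vectors of equal length.
#' @return ARI in \[-1, 1\].
#' @export
grouping_agreement <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("label vectors differ in length: ", length(predicted), " vs ",
         length(truth))
  mclust::adjustedRandIndex(predicted, truth)
}
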