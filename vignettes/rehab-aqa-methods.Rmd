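---
title: "Scoring rehabilitation exercises from skeleton sequences: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring rehabilitation exercises from skeleton sequences: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Action quality assessment (AQA) for rehabilitation asks: given a motion-capture
recording of a patient performing a prescribed exercise, predict the continuous
quality score a clinician would assign (0–100). The input for one repetition is
a skeleton sequence — per frame, the 3-D positions of J joints and their
orientations (unit quaternions from Kinect-style sensors, or Euler angles from
optical trackers). Two properties of rehabilitation movement drive the design
of this package's model:

* joints act in *functional groups* (an arm raise recruits shoulder, elbow,
  wrist together), but which joints cooperate varies between patients and
  exercises, so a fixed grouping or a fixed skeletal graph is too rigid;
* clinicians attend both to joint *trajectories* (positions) and to the
  *stability of the movement plane* (orientations), so both modalities carry
  complementary signal.

`d2sta` implements a dual-stream spatio-temporal network with motion-aware
dynamic joint grouping, plus everything around it: dataset loading and
preprocessing for KIMORE-style and UI-PRMD-style plain-text exports, a
synthetic-data generator with known ground truth, training with the published
optimisation recipes, and the standard evaluation metrics.

## Model

### Dual-stream backbone

Positions `(T, J, 3)` and orientations `(T, J, 4 or 3)` pass through two
independent streams of three STGCN blocks. One block is

1. a **spatial stage**: a 1×1 channel-mixing convolution, i.e. the same fully
   connected transform applied at every (frame, joint) site. Deliberately *no*
   skeletal adjacency matrix is used — the grouping module later learns
   inter-joint structure instead;
2. a **temporal stage**: a convolution over a 3-frame window (padding 1, block
   stride), batch-normalised;
3. a **residual connection** (identity when shapes match, a strided 1×1
   convolution + batch norm otherwise), followed by ReLU.

The channel schedule is 64 → 128 → 256 per stream with temporal strides
(1, 2, 2), so a 100-frame clip leaves the backbone with T′ = 25 frames. The
two streams are concatenated on the channel axis into a fused feature
`(T′, J, 512)`. Convolutions followed by batch norm carry no bias terms (the
norm's offset makes them redundant). With a single available modality
(`position_only` / `orientation_only`), the same input feeds both streams,
keeping the architecture unchanged.

### SADG: self-attention for dynamic groups

The grouping module turns *motion amplitude* into a soft joint partition:

* **Motion amplitude** `M[b, j, c]`: the population standard deviation of each
  fused feature channel along time — a proxy for each joint's range of motion.
* **Mask generator**: a two-layer MLP (hidden width d = 64, ReLU) maps `M` to
  G = 6 group logits per joint; a softmax over groups yields soft assignments
  α with `sum_g α[b, g, j] = 1`. Every joint belongs fractionally to all
  groups; nothing is discretised during learning.
* **Group projection**: `Xg[b,t,g,c] = sum_j α[b,g,j] x[b,t,j,c]` pools the J
  joints into G functional-group features.
* **Two-stage attention**: multi-head scaled-dot-product self-attention
  (H = 8 heads, head width D = C/H, logit scale 1/√D), first over the T′ time
  steps within each group (intra-group temporal modelling), then over the G
  groups at each time step (inter-group interaction). Each stage has learned
  Q/K/V and output projections and its own residual connection. The stage
  order is configurable (`stage_order`).
* **Back-projection**: the attended group features are redistributed to joints
  with the same mask, `Z[b,t,j,c] = sum_g z[b,t,g,c] α[b,g,j]`.
* **Output projection + module residual**: a learned C→C map on the
  back-projected tensor, added to the module input.

The final output projection is this package's own design choice: the module
needs a learned gate where its branch rejoins the trunk, because with a
uniform soft mask the projection/back-projection pair is a joint-averaging
operator, not zero. With the projection in place, zeroing all SADG weights
makes the module an exact identity — which is also what makes the no-SADG
ablation equivalence testable, and gives the module a clean "start near the
trunk, learn a correction" reading.

### Head and objective

Features are mean-pooled over time and joints (the minimal assumption — no
attention pooling is claimed), then scored by a two-layer head
512 → 128 → 1 (compression ratio 0.25) with a ReLU between. Training minimises
`(1/N) Σ ½(ŷ − y)²`; the ½ factor is kept literally (it only rescales
gradients). Scores are trained on the unit scale (labels divided by 100) by
default — the error magnitudes of published benchmarks are only consistent
with normalised targets — and `raw_0_100` is available. The head's output bias
starts at the midpoint of the score scale so early optimisation works on
ranking rather than on closing a constant offset. Predictions are unbounded
during training and clipped to the valid range at reporting time only.

## Preprocessing

* **Resampling**: every clip is cubic-spline interpolated to 100 frames
  (endpoint-preserving; at least 4 input frames required). Quaternions are
  renormalised after interpolation, with the scalar part kept non-negative to
  resolve the double cover.
* **Normalisation**: the KIMORE recipe z-scores each (joint, channel) using
  statistics pooled over frames of the *training split only*; standard
  deviations below 1e-6 are floored with a warning (frozen joints). The
  UI-PRMD recipe applies no normalisation, but unwraps Euler angles: sensors
  clamp angles to (−180°, 180°], and the loader restores continuity by adding
  the per-step multiple of 360° that minimises each consecutive jump.
* **Splitting**: stratified 8:1:1 train/validation/test on score-quantile bins
  (5 bins), largest-remainder rounding per bin, deterministic given a seed.

## The synthetic generator

`generate_synth()` plants exactly the structure the model claims to exploit.
Joints are partitioned into G = 6 contiguous groups; all joints of group g
oscillate coherently along a fixed unit direction u_g:

    pos(j, t) = rest(j) + s_i · A · sin(2π f_g t/T + φ_g) · u_g + ε,

with per-sample amplitude scale `s_i = 1 + N(0, 0.15)`, i.i.d. Gaussian
coordinate noise `ε ~ N(0, σ_i²)`, `σ_i ~ U(0, 0.15)`, and per-group
frequencies f_g = 1…G cycles per clip. Orientations are unit quaternions for
rotations about u_g with angle proportional to the same sinusoid (angle noise
is added before quaternionisation, so quaternions are exactly unit norm).
The quality score is the documented monotone function

    score_i = clip(100 · (1 − w_amp·|s_i − 1| − w_noise·σ_i), 0, 100),

with w_amp = 1 and w_noise = 2, chosen so typical scores span roughly 40–100 —
comparable to clinician scores on real cohorts. Because the score function is
known exactly, held-out recovery (Spearman correlation, MAD) has an objective
ground truth, and the planted partition gives the grouping module a measurable
target (adjusted Rand index of the argmax assignments).

What the generator deliberately does **not** emulate: biomechanical joint
limits, temporal autocorrelation in the noise, per-exercise score rubrics,
sensor dropout, or inter-subject anthropometric variation. Passing the
synthetic-recovery tests therefore demonstrates that the pipeline can learn a
planted amplitude/noise score from coordinated motion — not that it matches
clinician scores on real recordings, which requires the real datasets.

## Training

Two published recipes are pinned: KIMORE (AdamW, lr 1e-4, weight decay 1e-4,
batch 32, z-score preprocessing) and UI-PRMD (SGD, lr 0.1, no weight decay,
batch 1, no normalisation, orientation-only input). Both use cosine annealing
to 0 across the schedule; a linear decay variant is available. The default
epoch budget is 100 and the default seed 3407. The best checkpoint is selected
by validation MAD. Training aborts on a non-finite loss.

Two engines compute the same architecture:

* `engine = "reference"` — the double-precision R implementation, verified
  end-to-end against central finite differences (tolerance 1e-3 on relative
  error);
* `engine = "compiled"` — a single-precision C++ implementation used for
  larger runs; it agrees with the reference forward pass to float precision
  (~1e-7) and is several-fold faster. Both are deterministic given the seed;
  they differ in shuffling RNG and arithmetic precision, so their loss
  trajectories match closely but not bitwise.

### Problem sizes used in the shipped tests

The package's training-based tests run the generator's default conditions
(300 samples, T = 100, J = 25, 6 groups) with backbone widths reduced to
(64, 64, 128) — the config supports any schedule — under the KIMORE recipe,
three seeds with a 10-epoch budget each (the reproduction script runs one
such seed). On this problem the validation MAD typically crosses
the 0.08 (unit scale) threshold around epoch 5–7, so these budgets leave
headroom while keeping the runs fast; the published 100-epoch schedule is
unnecessary for the synthetic task.

## Evaluation

`metrics_report()` computes MAD, RMSE, MAPE (percent; errors on a zero true
score rather than silently adding an epsilon) and Spearman's rank correlation
(Pearson correlation of average ranks; NaN with a warning when either argument
is constant). MAD ≤ RMSE always holds; MAPE is scale-invariant; SRC is
invariant under strictly monotone transforms. Metrics are reported on
whichever score scale the evaluation uses, never silently mixed.

## Numerical choices and edge cases

* Batch-norm epsilon 1e-5, momentum 0.1, running variance stored with the
  unbiased factor; evaluation always uses running statistics.
* Motion-amplitude gradients treat exactly-zero amplitudes as having zero
  subgradient.
* Softmaxes are max-shifted before exponentiation.
* The attention logit scale defaults to 1/√D; a printed variant (1/C) would
  collapse logits at C = 512, so the conventional scaling is the default and
  the scale is exposed in `sadg_config()`.
* The mask generator's output layer is initialised with enough gain that the
  group logits start with unit-order dispersion. With a standard small-gain
  init the softmax over groups starts so flat that every joint shares the
  same argmax group, and at the published learning rate (1e-4) the assignment
  differentiates only after tens of epochs; the higher-gain start makes the
  soft assignment responsive to motion-amplitude differences from the first
  epochs without changing what is learned.
* Angle unwrapping assumes true inter-frame motion below 180°; faster motion
  is unrecoverable from wrapped measurements.
* `resample_cubic()` with `target_len` equal to the input length reproduces
  the input to numerical precision.
* Ties in rank correlation use average ranks.

## Known limitations

* The spatial stage carries no anatomical prior; on very small datasets a
  skeletal-graph convolution may generalise better.
* The motion-amplitude statistic does not normalise displacement by body
  topology, so low-amplitude but clinically critical joints (e.g. cervical
  spine) contribute weak grouping signal.
* Soft group assignments remain genuinely soft after training; the argmax
  partition is informative (it recovers planted groups well above chance on
  synthetic data), but α is not a hard clustering and should not be read as
  one. Grouping recovery is also not monotone in training time: it peaks in
  the first dozen epochs and partially dissolves as the regression objective
  dominates, consistent with the near-uniform trained assignment tables
  reported for this architecture on real data.
* The compiled engine covers the full SADG model with batch norm on the unit
  score scale; ablation variants train on the reference engine.
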