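# d2sta — dual-stream spatio-temporal attention for rehabilitation exercise scoring

`d2sta` scores the quality of rehabilitation exercises from skeleton
sequences. Given per-frame 3-D joint positions and joint orientations
(quaternions or Euler angles) for one exercise repetition, it regresses the
continuous quality score (0–100) a clinician would assign.

The model at its core:

* a **dual-stream STGCN backbone** — positions `X_pos ∈ R^{T×J×3}` and
  orientations `X_ori ∈ R^{T×J×4}` pass through parallel stacks of three
  blocks (per-joint 1×1 channel-mixing convolution → batch norm → ReLU →
  3-frame temporal convolution → residual → ReLU), expanding channels
  64→128→256 per stream and downsampling time twice, then fused by channel
  concatenation: `X = Concat(X_pos, X_ori) ∈ R^{T/4 × J × 512}`;
* **SADG (self-attention for dynamic groups)** — the motion amplitude
  `M[j,c] = sd_t(X[t,j,c])` (a range-of-motion proxy) drives a learnable mask
  generator `α = softmax_g(W2·ReLU(W1·M + b1) + b2)` that soft-assigns the J
  joints to G = 6 functional groups; joint features are pooled into groups
  (`Xg = Σ_j α_gj X_j`), modelled by two stages of multi-head scaled
  dot-product self-attention (over time within each group, then across groups
  at each time step, H = 8 heads), and redistributed to joints with the same
  mask, with a residual path around the whole module;
* a **regression head** `512 → 128 → 1` with ReLU, trained with the loss
  `L = (1/N) Σ ½‖ŷ − y‖²`, evaluated with MAD, RMSE, MAPE and Spearman's
  rank correlation.

Around the model the package provides dataset loading/validation for
KIMORE-style and UI-PRMD-style plain-text exports (cubic resampling to 100
frames, z-score or angle-unwrap preprocessing, stratified 8:1:1 splits), a
synthetic generator with planted functional groups and a known score
function, the two published optimisation recipes (AdamW and SGD with cosine
annealing), and a compiled single-precision training engine for CPU runs.

## Worked example

```r
library(d2sta)

# synthetic cohort: 300 repetitions, 25 joints, 100 frames, 6 planted groups
dataset <- generate_synth(synth_config(n_samples = 300, seed = 7))
split   <- stratified_split(dataset$true_params, seed = 7)
data    <- prepare_splits(dataset$samples, split, recipe = "kimore")

run <- train_model(model_config(channels = c(64, 64, 128)),
                   train_config("kimore", epochs = 10, seed = 1),
                   data)

evaluate_model(run$model, data$test)
#> metric      value
#> MAD        0.0406
#> RMSE       0.0566
#> MAPE       6.7166
#> SRC        0.9475
#> n              30
```

On the unit score scale (scores/100), a test MAD of 0.041 means predictions
are on average 4 score points from the known ground truth, and an SRC of 0.95
means the model ranks repetitions almost exactly as the planted quality
ordering. The learned grouping can be inspected as a `J × G` table of mean
assignment probabilities:

```r
am <- inspect_groups(run$model, data$test$positions, data$test$orientations,
                     joint_names = dataset$joint_names)
grouping_agreement(apply(am, 1, which.max), dataset$true_groups)
#> [1] 0.4295
```

an adjusted Rand index far above the random-partition null (whose 95th
percentile is ≈ 0.11 for 25 joints in 6 groups).

A thin command-line interface over these functions ships in
`inst/cli/d2sta.R` (`synth`, `train`, `eval`, `inspect-groups` subcommands)
for running the same pipeline on on-disk datasets.

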