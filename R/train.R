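# Training loop: optimisation recipes, cosine/linear learning-rate
# schedules, seeding, per-epoch validation, best-checkpoint tracking and
# evaluation.

#' Training configuration
#'
#' `recipe = "kimore"` fixes AdamW, lr 1e-4, weight decay 1e-4, batch 32;
#' `recipe = "uiprmd"` fixes SGD, lr 0.1, no weight decay, batch 1;
#' `recipe = "custom"` takes the arguments as given.
#'
#' @param recipe One of `"kimore"`, `"uiprmd"`, `"custom"`.
#' @param optimizer `"adamw"` or `"sgd"`.
#' @param lr Initial learning rate.
#' @param weight_decay Decoupled weight decay (AdamW) / L2 (SGD).
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param scheduler `"cosine_annealing"` (to `lr_min` by the final epoch) or
#'   `"linear"` (constant decrement `linear_decay` per epoch, floored at
#'   `lr_min`).
#' @param lr_min Scheduler floor.
#' @param linear_decay Per-epoch decrement for the linear scheduler.
#' @param seed RNG seed controlling init and shuffling (default 3407).
#' @return list of class `train_config`.
#' @export
train_config <- function(recipe = c("kimore", "uiprmd", "custom"),
                         optimizer = c("adamw", "sgd"), lr = 1e-4,
                         weight_decay = 1e-4, batch_size = 32L,
                         epochs = 100L,
                         scheduler = c("cosine_annealing", "linear"),
                         lr_min = 0, linear_decay = 1e-4, seed = 3407L) {
  recipe <- match.arg(recipe)
  optimizer <- match.arg(optimizer)
  scheduler <- match.arg(scheduler)
  if (recipe == "kimore") {
    optimizer <- "adamw"; lr <- 1e-4; weight_decay <- 1e-4; batch_size <- 32L
  } else if (recipe == "uiprmd") {
    optimizer <- "sgd"; lr <- 0.1; weight_decay <- 0; batch_size <- 1L
  }
  structure(list(recipe = recipe, optimizer = optimizer, lr = lr,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), scheduler = scheduler,
                 lr_min = lr_min, linear_decay = linear_decay,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' @param cfg A [train_config()].
#' @param epoch Zero-based epoch index.
#' @return The scheduled learning rate; `lr` at epoch 0, decreasing to the
#'   floor by the final epoch.
#' @export
scheduled_lr <- function(cfg, epoch) {
  if (cfg$scheduler == "cosine_annealing") {
    if (cfg$epochs <= 1) return(cfg$lr)
    cfg$lr_min + 0.5 * (cfg$lr - cfg$lr_min) *
      (1 + cos(pi * epoch / (cfg$epochs - 1)))
  } else {
    max(cfg$lr - cfg$linear_decay * epoch, cfg$lr_min)
  }
}

# ---- optimizers (operate on flat leaf lists) --------------------------------

#' @keywords internal
adamw_step <- function(params, grads, opt, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  step_leaf <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * ((m / bc1) / (sqrt(v / bc2) + eps)) - lr * wd * p
    list(p = p, m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      keys <- if (is.null(names(p))) seq_along(p) else names(p)
      res <- lapply(keys, function(k) walk(p[[k]], g[[k]], m[[k]], v[[k]]))
      pp <- lapply(res, `[[`, "p"); names(pp) <- names(p)
      mm <- lapply(res, `[[`, "m"); names(mm) <- names(p)
      vv <- lapply(res, `[[`, "v"); names(vv) <- names(p)
      list(p = pp, m = mm, v = vv)
    } else step_leaf(p, g, m, v)
  }
  r <- walk(params, grads, opt$m, opt$v)
  list(params = r$p, opt = list(t = opt$t, m = r$m, v = r$v))
}

#' @keywords internal
sgd_step <- function(params, grads, opt, lr, wd) {
  params <- tree_map(function(p, g) p - lr * (g + wd * p), params, grads)
  list(params = params, opt = opt)
}

#' @keywords internal
init_opt_state <- function(params, optimizer) {
  if (optimizer == "adamw")
    list(t = 0, m = tree_zero(params), v = tree_zero(params))
  else list()
}

# ---- data preparation -------------------------------------------------------

#' Preprocess samples into train/val/test tensors
#'
#' Applies the recipe's normalisation (z-score fitted on the training split
#' for the KIMORE recipe; none for UI-PRMD) and rescales scores to the
#' model's score scale.
#'
#' @param samples Named list of `skeleton_sample`s.
#' @param split A `split_assignment`.
#' @param recipe `"kimore"`, `"uiprmd"` or `"custom"` (no normalisation).
#' @param score_scale `"unit_interval"` or `"raw_0_100"`.
#' @return list with `train`, `val`, `test` tensor sets (see
#'   [samples_to_tensors()]) and the fitted `norm_stats` (or NULL).
#' @export
prepare_splits <- function(samples, split, recipe = "kimore",
                           score_scale = "unit_interval") {
  pick <- function(ids) samples[ids]
  tr <- pick(split$train_ids)
  stats <- NULL
  if (recipe == "kimore") {
    stats <- fit_zscore(tr)
    samples <- lapply(samples, apply_zscore, stats = stats)
  }
  mk <- function(ids) {
    if (length(ids) == 0) return(NULL)
    tt <- samples_to_tensors(samples[ids])
    if (score_scale == "unit_interval") tt$scores <- tt$scores / 100
    tt
  }
  list(train = mk(split$train_ids), val = mk(split$val_ids),
       test = mk(split$test_ids), norm_stats = stats)
}

# ---- training ---------------------------------------------------------------

#' Train a scoring model
#'
#' Minimises the half-MSE objective with the configured optimizer and
#' learning-rate schedule; tracks per-epoch training loss and validation
#' MAD and keeps the parameters of the best validation epoch.  Fully
#' deterministic given `tcfg$seed`.
#'
#' @param mcfg A [model_config()].
#' @param tcfg A [train_config()].
#' @param data Prepared tensors as returned by [prepare_splits()] (elements
#'   `train` and, optionally, `val`).
#' @param verbose Print per-epoch progress.
#' @param engine `"reference"` runs the double-precision R implementation;
#'   `"compiled"` runs the single-precision compiled engine (several-fold
#'   faster, identical architecture, float arithmetic); `"auto"` picks the
#'   compiled engine whenever the configuration supports it (full SADG
#'   model, batch norm, unit score scale).
#' @return list of class `run_record`: `model` (best checkpoint),
#'   `train_loss`, `val_mad` (per epoch), `best_epoch`, `lr_schedule`,
#'   `config`, `seed`, `engine`.
#' @export
train_model <- function(mcfg, tcfg, data, verbose = FALSE,
                        engine = c("auto", "reference", "compiled")) {
  engine <- match.arg(engine)
  compiled_ok <- mcfg$ablation %in% c("none", "position_only",
                                      "orientation_only") &&
    mcfg$batchnorm && mcfg$score_scale == "unit_interval"
  if (engine == "auto") engine <- if (compiled_ok) "compiled" else "reference"
  if (engine == "compiled") {
    if (!compiled_ok)
      stop("the compiled engine supports the full SADG model with batch ",
           "norm on the unit score scale; use engine = \"reference\"")
    return(train_model_compiled(mcfg, tcfg, data, verbose))
  }
  set.seed(tcfg$seed)
  model <- init_model(mcfg)
  opt <- init_opt_state(model$params, tcfg$optimizer)
  ntr <- dim(data$train$positions)[1]
  if (ntr == 0) stop("empty training split")
  has_val <- !is.null(data$val) && dim(data$val$positions)[1] > 0
  train_loss <- numeric(tcfg$epochs)
  val_mad <- rep(NA_real_, tcfg$epochs)
  lr_schedule <- numeric(tcfg$epochs)
  best <- list(mad = Inf, params = model$params, state = model$state,
               epoch = 0L)
  for (epoch in seq_len(tcfg$epochs)) {
    lr <- scheduled_lr(tcfg, epoch - 1)
    lr_schedule[epoch] <- lr
    ord <- sample.int(ntr)
    batches <- split(ord, ceiling(seq_along(ord) / tcfg$batch_size))
    eloss <- 0
    for (idx in batches) {
      pos <- data$train$positions[idx, , , , drop = FALSE]
      ori <- data$train$orientations[idx, , , , drop = FALSE]
      y <- data$train$scores[idx]
      fw <- model_fwd(model, pos, ori, training = TRUE)
      model$state <- fw$state
      loss <- mse_loss(fw$y, y)
      if (!is.finite(loss))
        stop("training diverged: non-finite loss at epoch ", epoch)
      eloss <- eloss + loss * length(idx)
      dy <- (fw$y - y) / length(y)
      bw <- model_bwd(model, fw$cache, dy)
      if (lr > 0) {
        st <- if (tcfg$optimizer == "adamw")
          adamw_step(model$params, bw$grads, opt, lr, tcfg$weight_decay)
        else sgd_step(model$params, bw$grads, opt, lr, tcfg$weight_decay)
        model$params <- st$params
        opt <- st$opt
      }
    }
    train_loss[epoch] <- eloss / ntr
    if (has_val) {
      vp <- predict(model, data$val$positions, data$val$orientations,
                    batch_size = tcfg$batch_size)
      val_mad[epoch] <- mad_score(data$val$scores, vp)
      if (val_mad[epoch] < best$mad) {
        best <- list(mad = val_mad[epoch], params = model$params,
                     state = model$state, epoch = epoch)
      }
    }
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  loss %.5f  val MAD %s", epoch,
                      lr, train_loss[epoch],
                      ifelse(has_val, sprintf("%.4f", val_mad[epoch]), "-")))
  }
  if (!has_val) best <- list(mad = NA_real_, params = model$params,
                             state = model$state, epoch = tcfg$epochs)
  model$params <- best$params
  model$state <- best$state
  structure(list(model = model, train_loss = train_loss, val_mad = val_mad,
                 best_epoch = best$epoch, lr_schedule = lr_schedule,
                 model_config = mcfg, train_config = tcfg,
                 seed = tcfg$seed, engine = "reference"),
            class = "run_record")
}

# single-precision compiled training path (same architecture; see
# src/engine.cpp)
#' @keywords internal
train_model_compiled <- function(mcfg, tcfg, data, verbose = FALSE) {
  set.seed(tcfg$seed)
  model <- init_model(mcfg)
  tr <- data$train
  if (mcfg$ablation == "position_only") tr$orientations <- tr$positions
  if (mcfg$ablation == "orientation_only") tr$positions <- tr$orientations
  va <- data$val
  has_val <- !is.null(va) && dim(va$positions)[1] > 0
  if (has_val) {
    if (mcfg$ablation == "position_only") va$orientations <- va$positions
    if (mcfg$ablation == "orientation_only") va$positions <- va$orientations
  }
  scale <- mcfg$sadg$scale
  if (is.null(scale))
    scale <- 1 / sqrt(mcfg$fused_channels / mcfg$sadg$n_heads)
  lrs <- vapply(seq_len(tcfg$epochs) - 1, function(e) scheduled_lr(tcfg, e),
                0)
  r <- engineTrain(
    model$params, model$state, mcfg$pos_stream$block_strides,
    as.vector(tr$positions), dim(tr$positions),
    as.vector(tr$orientations), dim(tr$orientations),
    tr$scores,
    if (has_val) as.vector(va$positions) else numeric(),
    if (has_val) dim(va$positions) else c(0L, dim(tr$positions)[2:4]),
    if (has_val) as.vector(va$orientations) else numeric(),
    if (has_val) va$scores else numeric(),
    mcfg$sadg$n_groups, mcfg$sadg$n_heads, scale,
    tcfg$epochs, tcfg$batch_size, lrs, tcfg$weight_decay,
    tcfg$optimizer == "sgd", tcfg$seed)
  model$params <- r$best$params
  model$state <- r$best$state
  if (verbose)
    message(sprintf("compiled engine: %d epochs, best val MAD %.4f at %d",
                    tcfg$epochs, suppressWarnings(min(r$val_mad, na.rm = TRUE)),
                    r$best_epoch))
  structure(list(model = model, train_loss = as.numeric(r$train_loss),
                 val_mad = as.numeric(r$val_mad),
                 best_epoch = as.integer(r$best_epoch), lr_schedule = lrs,
                 model_config = mcfg, train_config = tcfg,
                 seed = tcfg$seed, engine = "compiled"),
            class = "run_record")
}

#' @export
print.run_record <- function(x, ...) {
  cat("<run_record>", length(x$train_loss), "epochs; final loss",
      sprintf("%.5f", utils::tail(x$train_loss, 1)), "\n")
  if (any(!is.na(x$val_mad)))
    cat("  best val MAD", sprintf("%.4f", min(x$val_mad, na.rm = TRUE)),
        "at epoch", x$best_epoch, "\n")
  invisible(x)
}

#' Evaluate a model on a tensor set
#'
#' Pure (no weight updates, running-statistics batch norm); predictions are
#' clipped to the valid score range at reporting time only.
#'
#' @param model A `d2sta_model`.
#' @param tensors list with `positions`, `orientations`, `scores`.
#' @param clip Clip predictions to the score range before computing metrics.
#' @return A `metrics_report`; the predictions are attached as attribute
#'   `"predictions"`.
#' @export
evaluate_model <- function(model, tensors, clip = TRUE) {
  yh <- predict(model, tensors$positions, tensors$orientations)
  if (clip) {
    hi <- if (model$config$score_scale == "unit_interval") 1 else 100
    yh <- pmin(pmax(yh, 0), hi)
  }
  rep_ <- metrics_report(tensors$scores, yh)
  attr(rep_, "predictions") <- yh
  rep_
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS file holding parameters, batch-norm state
#' and the full model config; loading verifies that weight shapes agree
#' with the config.
#'
#' @param model A `d2sta_model`.
#' @param path File path.
#' @return `save_checkpoint`: the path, invisibly.  `load_checkpoint`: the
#'   restored `d2sta_model`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config, params = model$params,
               state = model$state), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  ref <- init_model(ck$config, seed = 0L)
  shp <- function(t) tree_map(function(x) paste(dim(x) %||% length(x),
                                                collapse = "x"), t)
  if (!identical(shp(ref$params), shp(ck$params)))
    stop("checkpoint weight shapes disagree with its config")
  structure(list(config = ck$config, params = ck$params, state = ck$state),
            class = "d2sta_model")
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build an ablated model configuration
#'
#' @param base A [model_config()] to modify.
#' @param no_sadg Remove the SADG block entirely.
#' @param mhsa_only Replace SADG by plain multi-head self-attention over
#'   joints (no grouping).
#' @param position_only,orientation_only Feed a single modality to both
#'   backbone streams.
#' @return The modified `d2sta_config`.
#' @export
ablate <- function(base = model_config(), no_sadg = FALSE,
                   mhsa_only = FALSE, position_only = FALSE,
                   orientation_only = FALSE) {
  if (no_sadg + mhsa_only > 1)
    stop("no_sadg and mhsa_only are mutually exclusive")
  if (position_only + orientation_only > 1)
    stop("position_only and orientation_only are mutually exclusive")
  if ((no_sadg || mhsa_only) && (position_only || orientation_only))
    stop("combine at most one SADG flag with at most one stream flag by ",
         "constructing the config directly")
  abl <- if (no_sadg) "no_sadg" else if (mhsa_only) "mhsa_only"
         else if (position_only) "position_only"
         else if (orientation_only) "orientation_only" else "none"
  model_config(in_pos = base$in_pos, in_ori = base$in_ori,
               channels = base$pos_stream$block_channels,
               strides = base$pos_stream$block_strides,
               n_groups = base$sadg$n_groups, n_heads = base$sadg$n_heads,
               mask_hidden = base$sadg$mask_hidden,
               attn_scale = base$sadg$scale,
               stage_order = base$sadg$stage_order,
               head_hidden = base$head_hidden,
               score_scale = base$score_scale, batchnorm = base$batchnorm,
               ablation = abl)
}
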