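# Reading, validating, preprocessing and splitting skeleton-sequence
# datasets laid out as plain-text numeric tables plus a CSV manifest
# (sample_id, position_path, orientation_path, exercise_id, score).  Sample
# files hold one frame per row; joints are ordered as in the manifest's
# joint names with channels fastest-varying (x, y, z of joint 1, then
# joint 2, ...).

#' Load a dataset manifest
#'
#' @param path CSV file with columns `sample_id`, `position_path`,
#'   `orientation_path`, `exercise_id`, `score`.  Relative sample paths are
#'   resolved against the manifest's directory.  An optional `joint_names`
#'   sidecar (one name per line, same directory, named
#'   `<manifest>.joints.txt`) provides joint labels.
#' @param orientation_kind `"quaternion"` (4 channels, w-first) or
#'   `"euler_deg"` (3 channels, degrees).
#' @return list of class `dataset_manifest` with `entries` (data.frame),
#'   `joint_names` (or NULL) and `orientation_kind`.
#' @export
load_manifest <- function(path, orientation_kind = c("quaternion",
                                                     "euler_deg")) {
  orientation_kind <- match.arg(orientation_kind)
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "position_path", "orientation_path",
            "exercise_id", "score")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("manifest is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in manifest: ",
         df$sample_id[duplicated(df$sample_id)][1])
  if (!is.numeric(df$score) || any(!is.finite(df$score)) ||
      any(df$score < 0 | df$score > 100))
    stop("scores must be finite numbers in [0, 100]")
  base <- dirname(path)
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  df$position_path <- resolve(df$position_path)
  df$orientation_path <- resolve(df$orientation_path)
  for (i in seq_len(nrow(df))) {
    for (col in c("position_path", "orientation_path")) {
      if (!file.exists(df[[col]][i]))
        stop("file listed for sample_id '", df$sample_id[i],
             "' does not exist: ", df[[col]][i])
    }
  }
  jn_path <- paste0(sub("\\.csv$", "", path), ".joints.txt")
  joint_names <- if (file.exists(jn_path)) readLines(jn_path) else NULL
  structure(list(entries = df, joint_names = joint_names,
                 orientation_kind = orientation_kind),
            class = "dataset_manifest")
}

#' @keywords internal
read_numeric_table <- function(path) {
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, data.table = FALSE),
    error = function(e) stop("cannot parse numeric table ", path, ": ",
                             conditionMessage(e)))
  m <- as.matrix(dt)
  if (!is.numeric(m)) {
    bad <- which(!apply(dt, 1, function(r) all(!is.na(suppressWarnings(
      as.numeric(r))))))[1]
    stop("non-numeric cell in ", path, " at row ", bad)
  }
  if (anyNA(m)) stop("missing/NaN values in ", path, " at row ",
                     which(rowSums(is.na(m)) > 0)[1])
  m
}

#' Load one skeleton sample
#'
#' @param entry One row of a manifest `entries` data.frame (or a list with
#'   the same fields).
#' @param orientation_kind `"quaternion"` or `"euler_deg"`.
#' @param frame_rate_hz Metadata only; default 30.
#' @return list of class `skeleton_sample` with `positions` `(T, J, 3)`,
#'   `orientations` `(T, J, Do)`, `score`, `sample_id`, `exercise_id`.
#'   Quaternions are renormalised to unit norm with non-negative scalar
#'   part.
#' @export
load_sample <- function(entry, orientation_kind = c("quaternion",
                                                    "euler_deg"),
                        frame_rate_hz = 30) {
  orientation_kind <- match.arg(orientation_kind)
  Do <- if (orientation_kind == "quaternion") 4L else 3L
  pm <- read_numeric_table(entry$position_path)
  om <- read_numeric_table(entry$orientation_path)
  if (nrow(pm) != nrow(om))
    stop("frame count mismatch for sample '", entry$sample_id, "': ",
         nrow(pm), " position rows vs ", nrow(om), " orientation rows")
  if (ncol(pm) %% 3L != 0L)
    stop("position table of sample '", entry$sample_id,
         "' has ", ncol(pm), " columns, not a multiple of 3")
  J <- ncol(pm) %/% 3L
  if (ncol(om) != J * Do)
    stop("orientation table of sample '", entry$sample_id, "' has ",
         ncol(om), " columns; expected ", J * Do)
  Tn <- nrow(pm)
  # row-major (frame) file layout -> (T, J, C) with channels fastest varying
  positions <- aperm(array(t(pm), c(3L, J, Tn)), c(3, 2, 1))
  orientations <- aperm(array(t(om), c(Do, J, Tn)), c(3, 2, 1))
  s <- list(sample_id = as.character(entry$sample_id),
            exercise_id = as.character(entry$exercise_id),
            positions = positions, orientations = orientations,
            score = as.numeric(entry$score),
            orientation_kind = orientation_kind,
            frame_rate_hz = frame_rate_hz)
  class(s) <- "skeleton_sample"
  if (orientation_kind == "quaternion") s <- normalize_quaternions(s)
  s
}

#' @keywords internal
normalize_quaternions <- function(sample) {
  q <- sample$orientations
  d <- dim(q)
  qm <- matrix(q, d[1] * d[2], 4L)
  nrm <- sqrt(rowSums(qm^2))
  if (any(nrm < 1e-8)) stop("zero-norm quaternion in sample ",
                            sample$sample_id)
  qm <- qm / nrm
  flip <- qm[, 1] < 0                          # resolve double cover: w >= 0
  qm[flip, ] <- -qm[flip, ]
  sample$orientations <- array(qm, d)
  sample
}

#' Unwrap a wrapped angle series
#'
#' Sensor angles bounded to (-180, 180] degrees jump by ~360 when the true
#' angle crosses the boundary; this restores a continuous series by adding
#' the per-step multiple of 360 that minimises each consecutive jump.  The
#' first element is unchanged and the output is congruent to the input
#' modulo 360 elementwise.
#'
#' @param series Numeric vector of angles in degrees.
#' @return Numeric vector, consecutive differences all within \[-180, 180\].
#' @export
unwrap_angles <- function(series) {
  n <- length(series)
  if (n < 2L) return(series)
  d <- diff(series)
  adj <- d - 360 * round(d / 360)
  series[1] + c(0, cumsum(adj))
}

#' Unwrap every Euler-angle channel of a sample
#'
#' @param sample A `skeleton_sample` with `orientation_kind = "euler_deg"`.
#' @return The sample with all orientation channels unwrapped over time.
#' @export
unwrap_sample <- function(sample) {
  if (sample$orientation_kind != "euler_deg")
    stop("angle unwrapping applies to Euler-angle orientations only")
  q <- sample$orientations
  d <- dim(q)
  qm <- matrix(aperm(q, c(1, 2, 3)), d[1], d[2] * d[3])
  for (k in seq_len(ncol(qm))) qm[, k] <- unwrap_angles(qm[, k])
  sample$orientations <- array(qm, d)
  sample
}

#' Resample a sample to a fixed clip length by cubic interpolation
#'
#' Every (joint, channel) series is interpolated with a cubic spline on the
#' uniform grid `seq(1, T, length.out = target_len)`; endpoints are
#' reproduced exactly and quaternions are renormalised afterwards.
#'
#' @param sample A `skeleton_sample` with at least 4 frames.
#' @param target_len Output clip length (default 100).
#' @return The resampled `skeleton_sample`.
#' @export
resample_cubic <- function(sample, target_len = 100L) {
  Tn <- dim(sample$positions)[1]
  if (Tn < 4L)
    stop("cubic resampling needs at least 4 frames, got ", Tn)
  xout <- seq(1, Tn, length.out = target_len)
  interp <- function(arr) {
    d <- dim(arr)
    m <- matrix(arr, d[1], d[2] * d[3])
    out <- matrix(0, target_len, ncol(m))
    for (k in seq_len(ncol(m)))
      out[, k] <- stats::spline(seq_len(d[1]), m[, k], xout = xout,
                                method = "fmm")$y
    array(out, c(target_len, d[2], d[3]))
  }
  sample$positions <- interp(sample$positions)
  sample$orientations <- interp(sample$orientations)
  if (sample$orientation_kind == "quaternion")
    sample <- normalize_quaternions(sample)
  sample
}

#' Fit z-score normalisation statistics
#'
#' Per-(joint, channel) mean and population standard deviation pooled over
#' all frames of the given (training) samples, separately for positions and
#' orientations.  Standard deviations below `floor` are floored with a
#' warning so frozen channels do not blow up the transform.
#'
#' @param train_samples list of `skeleton_sample`s (training split only).
#' @param floor Minimum allowed standard deviation.
#' @return list of class `norm_stats` with `pos`/`ori` mean and sd matrices
#'   (J x C) and the ids the stats were fitted on.
#' @export
fit_zscore <- function(train_samples, floor = 1e-6) {
  stopifnot(length(train_samples) > 0)
  one <- function(get) {
    d <- dim(get(train_samples[[1]]))
    acc_s <- matrix(0, d[2], d[3]); acc_q <- matrix(0, d[2], d[3]); n <- 0
    for (s in train_samples) {
      a <- get(s)
      n <- n + dim(a)[1]
      acc_s <- acc_s + apply(a, c(2, 3), sum)
      acc_q <- acc_q + apply(a * a, c(2, 3), sum)
    }
    mean <- acc_s / n
    v <- acc_q / n - mean^2
    sd <- sqrt(pmax(v, 0))
    if (any(sd < floor)) {
      warning(sum(sd < floor), " zero-variance channel(s); sd floored at ",
              floor)
      sd[sd < floor] <- floor
    }
    list(mean = mean, sd = sd)
  }
  structure(list(pos = one(function(s) s$positions),
                 ori = one(function(s) s$orientations),
                 fitted_on = vapply(train_samples, `[[`, "", "sample_id")),
            class = "norm_stats")
}

#' Apply (or invert) a z-score transform
#'
#' @param sample A `skeleton_sample`.
#' @param stats A `norm_stats` from [fit_zscore()].
#' @param invert Undo the transform instead.
#' @return The transformed sample.
#' @export
apply_zscore <- function(sample, stats, invert = FALSE) {
  tr <- function(a, st) {
    d <- dim(a)
    mu <- rep(as.vector(st$mean), each = d[1])
    sd <- rep(as.vector(st$sd), each = d[1])
    if (invert) array(as.vector(a) * sd + mu, d)
    else array((as.vector(a) - mu) / sd, d)
  }
  sample$positions <- tr(sample$positions, stats$pos)
  sample$orientations <- tr(sample$orientations, stats$ori)
  sample
}

#' Stratified train/validation/test split
#'
#' Samples are binned into score quantile bins (at most `n_bins`) and each
#' bin is partitioned according to `ratios` by largest-remainder rounding,
#' so per-stratum proportions are within one sample of the targets and the
#' overall split is an exact partition.  Deterministic given `seed`.
#'
#' @param manifest A `dataset_manifest`, or any data.frame with `sample_id`
#'   and `score` columns.
#' @param ratios Train/val/test fractions summing to 1.
#' @param seed Integer RNG seed.
#' @param n_bins Number of score quantile bins.
#' @return list of class `split_assignment` with `train_ids`, `val_ids`,
#'   `test_ids`, `seed`, `ratios`.
#' @export
stratified_split <- function(manifest, ratios = c(0.8, 0.1, 0.1), seed = 1L,
                             n_bins = 5L) {
  if (abs(sum(ratios) - 1) > 1e-8 || length(ratios) != 3)
    stop("ratios must be three fractions summing to 1")
  df <- if (inherits(manifest, "dataset_manifest")) manifest$entries
        else manifest
  stopifnot(all(c("sample_id", "score") %in% names(df)))
  ids <- as.character(df$sample_id)
  qs <- stats::quantile(df$score, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE)
  brk <- unique(qs)
  bin <- if (length(brk) < 2) rep(1L, nrow(df))
         else cut(df$score, breaks = brk, include.lowest = TRUE,
                  labels = FALSE)
  out <- list(train = character(), val = character(), test = character())
  rng <- local({ set.seed(seed); function(n) sample.int(n) })
  tgt_total <- length(ids) * ratios
  alloc <- c(0, 0, 0)
  for (b in sort(unique(bin))) {
    bids <- ids[bin == b]
    bids <- bids[rng(length(bids))]
    n <- length(bids)
    tgt <- n * ratios
    base <- floor(tgt)
    rem <- tgt - base
    left <- n - sum(base)
    if (left > 0) {
      # leftover slots go to the splits with the largest fractional
      # remainder, biased by how far each split lags its GLOBAL target so
      # small strata do not systematically starve the same split
      deficit <- pmax(tgt_total - alloc - base, 0) / pmax(tgt_total, 1)
      ord <- order(rem + deficit, decreasing = TRUE)
      base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
    }
    alloc <- alloc + base
    cuts <- cumsum(base)
    out$train <- c(out$train, bids[seq_len(base[1])])
    out$val <- c(out$val, if (base[2] > 0) bids[(cuts[1] + 1):cuts[2]])
    out$test <- c(out$test, if (base[3] > 0) bids[(cuts[2] + 1):cuts[3]])
  }
  structure(list(train_ids = out$train, val_ids = out$val,
                 test_ids = out$test, seed = as.integer(seed),
                 ratios = ratios),
            class = "split_assignment")
}

#' Load all samples of a manifest
#'
#' @param manifest A `dataset_manifest`.
#' @param target_len Resample every sample to this clip length (NULL to
#'   keep native lengths).
#' @param unwrap Apply angle unwrapping (Euler datasets).
#' @return Named list of `skeleton_sample`s.
#' @export
load_samples <- function(manifest, target_len = 100L, unwrap = FALSE) {
  out <- lapply(seq_len(nrow(manifest$entries)), function(i) {
    s <- load_sample(manifest$entries[i, ], manifest$orientation_kind)
    if (unwrap && manifest$orientation_kind == "euler_deg")
      s <- unwrap_sample(s)
    if (!is.null(target_len) && dim(s$positions)[1] != target_len)
      s <- resample_cubic(s, target_len)
    s
  })
  names(out) <- manifest$entries$sample_id
  out
}

#' Stack samples into model input tensors
#'
#' @param samples list of `skeleton_sample`s with equal T, J, Do.
#' @return list with `positions` `(n, T, J, 3)`, `orientations`
#'   `(n, T, J, Do)` and `scores` (raw 0-100 scale).
#' @export
samples_to_tensors <- function(samples) {
  n <- length(samples)
  dp <- dim(samples[[1]]$positions)
  do_ <- dim(samples[[1]]$orientations)
  pos <- array(0, c(n, dp))
  ori <- array(0, c(n, do_))
  for (i in seq_len(n)) {
    pos[i, , , ] <- samples[[i]]$positions
    ori[i, , , ] <- samples[[i]]$orientations
  }
  list(positions = pos, orientations = ori,
       scores = vapply(samples, `[[`, 0, "score"))
}

#' Serialize normalisation statistics or a split assignment as JSON
#'
#' Plain-text companions of a training run, so preprocessing is exactly
#' reproducible.
#'
#' @param x A `norm_stats` or `split_assignment`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_json_record <- function(x, path) {
  stopifnot(inherits(x, c("norm_stats", "split_assignment")))
  obj <- unclass(x)
  obj$.class <- class(x)[1]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_json_record
#' @export
read_json_record <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$.class
  obj$.class <- NULL
  if (identical(cls, "norm_stats")) {
    for (mod in c("pos", "ori")) {
      obj[[mod]]$mean <- as.matrix(obj[[mod]]$mean)
      obj[[mod]]$sd <- as.matrix(obj[[mod]]$sd)
    }
  }
  if (identical(cls, "split_assignment")) {
    for (k in c("train_ids", "val_ids", "test_ids"))
      obj[[k]] <- as.character(unlist(obj[[k]]))   # empty array -> chr(0)
  }
  structure(obj, class = cls)
}
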