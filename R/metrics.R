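# Evaluation metrics for score regression: mean absolute deviation, root
# mean squared error, mean absolute percentage error and Spearman's rank
# correlation (Pearson correlation of average ranks).

#' Mean absolute deviation
#' @param y,y_hat Equal-length numeric vectors (truth, prediction).
#' @return `(1/N) * sum(|y - y_hat|)`.
#' @export
mad_score <- function(y, y_hat) {
  check_pair(y, y_hat)
  mean(abs(y - y_hat))
}

#' Root mean squared error
#' @inheritParams mad_score
#' @return `sqrt(mean((y - y_hat)^2))`.
#' @export
rmse_score <- function(y, y_hat) {
  check_pair(y, y_hat)
  sqrt(mean((y - y_hat)^2))
}

#' Mean absolute percentage error
#'
#' @inheritParams mad_score
#' @return `(100/N) * sum(|(y - y_hat)/y|)` (percent).  Errors if any true
#'   value is exactly zero -- there is no silent epsilon.
#' @export
mape_score <- function(y, y_hat) {
  check_pair(y, y_hat)
  if (any(y == 0)) stop("MAPE undefined (division by zero): true value is ",
                        "zero at index ", which(y == 0)[1])
  100 * mean(abs((y - y_hat) / y))
}

#' Spearman's rank correlation
#'
#' Pearson correlation of the two rank vectors, ties resolved by average
#' ranks.  Returns NaN with a warning when either argument has zero rank
#' variance (all values tied).
#'
#' @inheritParams mad_score
#' @return Correlation in \[-1, 1\], or NaN for degenerate input.
#' @export
src_score <- function(y, y_hat) {
  check_pair(y, y_hat)
  if (length(y) < 2) stop("rank correlation needs at least 2 observations")
  ry <- rank(y, ties.method = "average")
  rh <- rank(y_hat, ties.method = "average")
  if (stats::var(ry) == 0 || stats::var(rh) == 0) {
    warning("rank correlation undefined: zero rank variance")
    return(NaN)
  }
  stats::cor(ry, rh)
}

#' @keywords internal
check_pair <- function(y, y_hat) {
  if (length(y) == 0) stop("empty input")
  if (length(y) != length(y_hat))
    stop("length mismatch: ", length(y), " vs ", length(y_hat))
  invisible(TRUE)
}

#' Full metrics report
#'
#' @inheritParams mad_score
#' @return list of class `metrics_report` with `mad`, `rmse`, `mape`, `src`
#'   and `n`.
#' @export
metrics_report <- function(y, y_hat) {
  structure(list(mad = mad_score(y, y_hat), rmse = rmse_score(y, y_hat),
                 mape = mape_score(y, y_hat),
                 src = if (length(y) >= 2) src_score(y, y_hat) else NA_real_,
                 n = length(y)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("%-6s %10s\n", "metric", "value"))
  for (m in c("mad", "rmse", "mape", "src"))
    cat(sprintf("%-6s %10.4f\n", toupper(m), x[[m]]))
  cat(sprintf("%-6s %10d\n", "n", x$n))
  invisible(x)
}
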