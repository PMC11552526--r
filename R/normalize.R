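#' Global statistics of one measurement block
#'
#' Pools all channels and frames of one (subject, side, wavelength) block and
#' returns its global mean, standard deviation (population convention,
#' divide by N), median, and first/third quartiles (linear interpolation
#' between order statistics, quantile `q` at fractional rank `q * (N - 1)`).
#'
#' @param block a `scan_block` or numeric matrix.
#' @return Named numeric vector `c(mean, std, median, p25, p75)`.
#' @export
#' @examples
#' global_stats(matrix(c(1, 5, 3, 7), 2, 2))
global_stats <- function(block) {
  x <- if (inherits(block, "scan_block")) block$values else block
  v <- as.vector(x)
  n <- length(v)
  m <- mean(v)
  qs <- unname(stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE))
  c(mean = m,
    std = sqrt(sum((v - m)^2) / n),
    median = qs[2], p25 = qs[1], p75 = qs[3])
}

norm_methods <- c("relative_change", "zscore", "zero_center", "robust")

#' Normalize one measurement block
#'
#' Continuous-wave transillumination yields uncalibrated intensities, so only
#' relative variations are meaningful; each block is rescaled by its own
#' global statistics (never across subjects or sides). Four methods are
#' supported:
#'
#' * `relative_change`: `x / mean`
#' * `zscore`: `(x - mean) / std`
#' * `zero_center`: `x - mean`
#' * `robust`: `(x - median) / (p75 - p25)`
#'
#' Statistics are the pooled global statistics of [global_stats()]. A
#' vanishing denominator (zero mean, zero spread) raises a degenerate-data
#' error rather than silently producing zeros: real detector data never has
#' exactly zero spread, so such inputs flag upstream bugs.
#'
#' @param block a `scan_block` or numeric matrix.
#' @param method one of `"relative_change"`, `"zscore"`, `"zero_center"`,
#'   `"robust"`.
#' @return Same type as `block`, with normalized values (shape preserved).
#' @export
#' @examples
#' normalize_block(matrix(c(1, 5, 3, 7), 2, 2), "zero_center")
normalize_block <- function(block, method = norm_methods) {
  method <- match.arg(method)
  is_block <- inherits(block, "scan_block")
  x <- if (is_block) block$values else block
  st <- global_stats(x)
  out <- switch(method,
    relative_change = {
      if (st[["mean"]] == 0)
        stop_degenerate("relative_change: global mean is zero")
      x / st[["mean"]]
    },
    zscore = {
      if (st[["std"]] == 0)
        stop_degenerate("zscore: global standard deviation is zero")
      (x - st[["mean"]]) / st[["std"]]
    },
    zero_center = x - st[["mean"]],
    robust = {
      iqr <- st[["p75"]] - st[["p25"]]
      if (iqr == 0)
        stop_degenerate("robust: interquartile range is zero")
      (x - st[["median"]]) / iqr
    })
  if (is_block) { block$values <- out; block } else out
}
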