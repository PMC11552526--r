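pool_methods <- c("rf", "tsd", "ssd", "tf", "sf")

# population standard deviation along matrix rows / columns
row_pop_sd <- function(x) {
  m <- rowMeans(x)
  sqrt(rowMeans((x - m)^2))
}
col_pop_sd <- function(x) {
  m <- colMeans(x)
  sqrt(colMeans((t(t(x) - m))^2))
}

#' Spatio-temporal feature pooling
#'
#' Reduces one channels-by-time block to a single feature vector. Five
#' methods:
#'
#' * `rf` ("raw features"): channel-major flattening — all frames of channel
#'   0, then channel 1, ... Length `R * T`.
#' * `tsd`: temporal standard deviation — per-channel population std over
#'   time. Length `R`.
#' * `ssd`: spatial standard deviation — per-frame population std over
#'   channels. Length `T`.
#' * `tf`: concatenation `c(tsd, ssd)`. Length `R + T`.
#' * `sf`: the six scalar spatio-temporal heterogeneity biomarkers of
#'   [sf_metrics()]. Length 6.
#'
#' @param block a `scan_block` or numeric matrix with at least 2 channels and
#'   2 frames.
#' @param method one of `"rf"`, `"tsd"`, `"ssd"`, `"tf"`, `"sf"`
#'   (case-insensitive).
#' @return Numeric feature vector.
#' @export
#' @examples
#' m <- matrix(c(1, 5, 3, 7), 2, 2)
#' pool(m, "tsd")  # per-channel std over time
#' pool(m, "rf")   # 1 3 5 7
pool <- function(block, method = pool_methods) {
  method <- match.arg(tolower(method), pool_methods)
  x <- if (inherits(block, "scan_block")) block$values else block
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop_degenerate(sprintf(
      "pooling needs at least 2 channels and 2 frames, got %dx%d",
      nrow(x), ncol(x)))
  switch(method,
    rf  = as.vector(t(x)),
    tsd = row_pop_sd(x),
    ssd = col_pop_sd(x),
    tf  = c(row_pop_sd(x), col_pop_sd(x)),
    sf  = sf_metrics(x))
}

#' Six scalar spatio-temporal heterogeneity biomarkers
#'
#' Composes mean/std reductions over the time and channel axes into six
#' scalars, in this canonical order:
#'
#' 1. spatial mean of the temporal std
#' 2. spatial std of the temporal std
#' 3. spatial std of the temporal mean
#' 4. temporal mean of the spatial std
#' 5. temporal std of the spatial std
#' 6. temporal std of the spatial mean
#'
#' These are the eight ordered mean/std compositions over the two axes minus
#' the two all-mean compositions (both equal the global mean, uninformative
#' after normalization). All standard deviations use the population
#' convention. A constant block returns the zero vector (all deviations
#' vanish; nothing divides by spread here).
#'
#' @param block a `scan_block` or numeric matrix with at least 2 channels and
#'   2 frames.
#' @return Numeric vector of length 6.
#' @export
#' @examples
#' sf_metrics(matrix(c(1, 5, 3, 7), 2, 2))  # 1 0 2 2 0 1
sf_metrics <- function(block) {
  x <- if (inherits(block, "scan_block")) block$values else block
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop_degenerate(sprintf(
      "sf_metrics needs at least 2 channels and 2 frames, got %dx%d",
      nrow(x), ncol(x)))
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  sigma_t <- row_pop_sd(x)   # length R
  mu_t    <- rowMeans(x)     # length R
  sigma_s <- col_pop_sd(x)   # length T
  mu_s    <- colMeans(x)     # length T
  c(mean(sigma_t), pop_sd(sigma_t), pop_sd(mu_t),
    mean(sigma_s), pop_sd(sigma_s), pop_sd(mu_s))
}
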