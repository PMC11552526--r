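#' ROC curve and AUC
#'
#' Sweeps thresholds over the distinct score values in descending order to
#' generate the ROC points from (0,0) to (1,1), and computes the AUC as the
#' Mann-Whitney statistic: the fraction of (positive, negative) pairs whose
#' scores are correctly ordered, ties counted one half. This equals the
#' trapezoidal area under the ROC points and is the probability that a
#' random positive case scores above a random negative one.
#'
#' @param scores numeric decision scores, higher = more positive.
#' @param labels binary labels (0/1), both classes present, same length.
#' @return An object of class `roc_result`: `points` (data.frame with
#'   `fpr`, `tpr`), `auc`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.3, 0.8, 0.2), c(1, 1, 0, 0))$auc  # 0.75
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop_validation("scores and labels must have equal length")
  if (any(!labels %in% c(0L, 1L)))
    stop_validation("labels must be 0/1")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop_undefined_auc("AUC undefined: only one class present")

  # Mann-Whitney via average ranks (ties counted 1/2)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  # ROC points: thresholds at distinct scores, descending
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))           # group equal scores
  tp <- cumsum(l); fp <- cumsum(1L - l)
  last <- !duplicated(grp, fromLast = TRUE)
  points <- data.frame(fpr = c(0, fp[last] / n_neg),
                       tpr = c(0, tp[last] / n_pos))
  structure(list(points = points, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f (%d positives, %d negatives, %d ROC points)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, add = FALSE, ...) {
  if (!add) {
    graphics::plot(x$points$fpr, x$points$tpr, type = "s",
                   xlab = "False positive rate", ylab = "True positive rate",
                   xlim = c(0, 1), ylim = c(0, 1), ...)
    graphics::abline(0, 1, lty = 3, col = "grey")
  } else {
    graphics::lines(x$points$fpr, x$points$tpr, type = "s", ...)
  }
  invisible(x)
}

# trapezoidal area under ROC points (internal; equals $auc by construction,
# asserted in the test suite)
trapezoid_area <- function(points) {
  sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                            utils::tail(points$tpr, -1)) / 2)
}
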