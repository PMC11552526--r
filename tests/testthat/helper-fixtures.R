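# Fixtures and independent brute-force oracles used across test files.
# Oracles are written with explicit loops, independently of the package's
# vectorized implementations.

# small random scan block (rows = sources x detectors)
make_block <- function(R = 4, T = 5, n_sources = R, n_detectors = 1,
                       wavelength_nm = 760, side = "left", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  scan_block(matrix(rnorm(R * T, mean = 10, sd = 2), R, T),
             n_sources = n_sources, n_detectors = n_detectors,
             wavelength_nm = wavelength_nm, side = side)
}

# subject record with four small random blocks
make_record <- function(id = "S1", n_sources = 4, n_detectors = 2, T = 6,
                        tumor_side = "none", seed = 1) {
  set.seed(seed)
  R <- n_sources * n_detectors
  blocks <- list()
  for (side in c("left", "right")) {
    for (wl in c(760, 830)) {
      blocks[[paste0(side, "_", wl)]] <- scan_block(
        matrix(rnorm(R * T, 10, 2), R, T), n_sources, n_detectors, wl, side)
    }
  }
  subject_record(id, blocks, cancer_positive = tumor_side != "none",
                 tumor_side = tumor_side)
}

make_cohort <- function(n = 3, n_sources = 4, n_detectors = 2, T = 6,
                        n_pos = 1, seed = 1) {
  records <- lapply(seq_len(n), function(i)
    make_record(sprintf("S%02d", i), n_sources, n_detectors, T,
                tumor_side = if (i <= n_pos) "left" else "none",
                seed = seed + i))
  cohort(records)
}

# ---- brute-force oracles -------------------------------------------------

bf_pop_sd <- function(v) {
  m <- sum(v) / length(v)
  s <- 0
  for (x in v) s <- s + (x - m)^2
  sqrt(s / length(v))
}

# normalization by explicit formulas over the pooled entries
bf_normalize <- function(mat, method) {
  v <- as.vector(mat)
  m <- mean(v)
  s <- bf_pop_sd(v)
  q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  out <- matrix(NA_real_, nrow(mat), ncol(mat))
  for (i in seq_len(nrow(mat))) {
    for (j in seq_len(ncol(mat))) {
      out[i, j] <- switch(method,
        relative_change = mat[i, j] / m,
        zscore = (mat[i, j] - m) / s,
        zero_center = mat[i, j] - m,
        robust = (mat[i, j] - q[2]) / (q[3] - q[1]))
    }
  }
  out
}

# pooling by explicit loops over axes
bf_pool <- function(mat, method) {
  R <- nrow(mat); T <- ncol(mat)
  tsd <- vapply(seq_len(R), function(r) bf_pop_sd(mat[r, ]), numeric(1))
  ssd <- vapply(seq_len(T), function(t) bf_pop_sd(mat[, t]), numeric(1))
  tmean <- vapply(seq_len(R), function(r) mean(mat[r, ]), numeric(1))
  smean <- vapply(seq_len(T), function(t) mean(mat[, t]), numeric(1))
  switch(method,
    rf = {
      out <- numeric(0)
      for (r in seq_len(R)) out <- c(out, mat[r, ])
      out
    },
    tsd = tsd,
    ssd = ssd,
    tf = c(tsd, ssd),
    sf = c(mean(tsd), bf_pop_sd(tsd), bf_pop_sd(tmean),
           mean(ssd), bf_pop_sd(ssd), bf_pop_sd(smean)))
}

# AUC by exhaustive pair counting, ties counted one half
bf_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    for (n in neg) {
      tot <- tot + (if (p > n) 1 else if (p == n) 0.5 else 0)
    }
  }
  tot / (length(pos) * length(neg))
}

# trapezoidal area under ROC points
bf_trapezoid <- function(points) {
  a <- 0
  for (i in seq_len(nrow(points) - 1)) {
    a <- a + (points$fpr[i + 1] - points$fpr[i]) *
      (points$tpr[i + 1] + points$tpr[i]) / 2
  }
  a
}
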