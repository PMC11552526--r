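test_that("the design-space enumeration has exactly 210 unique specs", {
  specs <- enumerate_specs()
  expect_length(specs, 210)
  keys <- vapply(specs, function(s)
    paste(paste(s$wavelengths, collapse = "+"),
          paste(s$normalizations, collapse = "+"), s$pooling), character(1))
  expect_identical(anyDuplicated(keys), 0L)
  # stable across calls
  expect_identical(vapply(enumerate_specs(), format, character(1)),
                   vapply(specs, format, character(1)))
})

test_that("restricting to single wavelengths and normalizations yields 40 specs", {
  specs <- Filter(function(s) length(s$wavelengths) == 1,
                  enumerate_specs(min_norms = 1, max_norms = 1))
  expect_length(specs, 40)
})

test_that("representation_spec validates and canonicalizes its fields", {
  s <- representation_spec(c(830, 760), c("zero_center", "relative_change"), "RF")
  expect_identical(s$wavelengths, c(760, 830))
  expect_identical(s$normalizations, c("relative_change", "zero_center"))
  expect_identical(s$pooling, "rf")
  expect_identical(format(s),
                   "A: 760, 830 nm; B: relative change + zero-centering; C: RF")
  expect_error(representation_spec(500, "zscore", "rf"),
               class = "bdot_validation_error")
  # the full set of four normalizations exceeds the default bound of three
  expect_error(
    representation_spec(760, c("relative_change", "zscore", "zero_center",
                               "robust"), "rf"),
    class = "bdot_validation_error")
})

test_that("unilateral representations have the advertised lengths and parts", {
  rec <- make_record(n_sources = 4, n_detectors = 2, T = 6, seed = 31)
  s1 <- representation_spec(760, "relative_change", "tsd")
  u1 <- build_unilateral(rec, "left", s1)
  expect_length(u1$values, 8)
  expect_length(u1$parts, 1)

  s2 <- representation_spec(c(760, 830), c("relative_change", "zero_center"), "rf")
  u2 <- build_unilateral(rec, "left", s2)
  expect_length(u2$values, 4 * 8 * 6)
  expect_length(u2$parts, 4)
  # canonical part order: wavelength outer, normalization inner
  expect_identical(
    vapply(u2$parts, function(p) paste(p$wavelength_nm, p$normalization),
           character(1)),
    c("760 relative_change", "760 zero_center",
      "830 relative_change", "830 zero_center"))

  s3 <- representation_spec(830, "zscore", "sf")
  expect_length(build_unilateral(rec, "right", s3)$values, 6)
})

test_that("length contract holds for all 210 specs on a small record", {
  rec <- make_record(n_sources = 8, n_detectors = 4, T = 16, seed = 32)
  R <- 32; T <- 16
  plen <- c(rf = R * T, tsd = R, ssd = T, tf = R + T, sf = 6)
  cache <- feature_cache()
  for (s in enumerate_specs()) {
    L <- length(s$wavelengths) * length(s$normalizations)
    u <- build_unilateral(rec, "left", s, cache)
    expect_identical(length(u$values), as.integer(L * plen[[s$pooling]]))
    b <- build_bilateral(rec, s, cache)
    expect_identical(length(b$values), as.integer(L))
  }
})

test_that("bilateral distances are nonnegative, symmetric and zero at equality", {
  rec <- make_record(n_sources = 4, n_detectors = 2, T = 6, seed = 33)
  spec <- representation_spec(c(760, 830), c("zscore", "robust"), "tf")
  b <- build_bilateral(rec, spec)
  expect_true(all(b$values >= 0))

  # identical sides -> all-zero vector
  rec_sym <- rec
  rec_sym$blocks$right_760$values <- rec_sym$blocks$left_760$values
  rec_sym$blocks$right_830$values <- rec_sym$blocks$left_830$values
  expect_equal(build_bilateral(rec_sym, spec)$values, rep(0, 4))

  # swapping sides leaves distances unchanged
  rec_sw <- rec
  for (wl in c(760, 830)) {
    l <- rec$blocks[[paste0("left_", wl)]]$values
    r <- rec$blocks[[paste0("right_", wl)]]$values
    rec_sw$blocks[[paste0("left_", wl)]]$values <- r
    rec_sw$blocks[[paste0("right_", wl)]]$values <- l
  }
  expect_equal(build_bilateral(rec_sw, spec)$values, b$values)
})

test_that("bilateral distance is the plain Euclidean norm of the part difference", {
  # engineer TSD parts: right - left = (3, 4, 0, ...) after zero-centering
  rec <- make_record(n_sources = 4, n_detectors = 1, T = 4, seed = 34)
  base <- matrix(10, 4, 4)
  left <- base; left[1, ] <- left[1, ] + c(-1, 1, -1, 1)       # tsd = (1,0,0,0)
  right <- base; right[1, ] <- right[1, ] + 4 * c(-1, 1, -1, 1) # tsd = (4,0,0,0)
  right[2, ] <- right[2, ] + 4 * c(-1, -1, 1, 1)               # tsd = (4,4,0,0)
  rec$blocks$left_760$values <- left
  rec$blocks$right_760$values <- right
  spec <- representation_spec(760, "zero_center", "tsd")
  d <- build_bilateral(rec, spec)$values
  # parts: left tsd = (1,0,0,0), right tsd = (4,4,0,0); ||(3,4,0,0)|| = 5
  expect_equal(d, 5)
})

test_that("bilateral distances satisfy the triangle inequality", {
  set.seed(35)
  spec <- representation_spec(760, "zscore", "tsd")
  mk <- function() matrix(rnorm(24, 10, 3), 4, 6)
  A <- mk(); B <- mk(); C <- mk()
  dist_ab <- function(x, y) sqrt(sum((pool(normalize_block(x, "zscore"), "tsd") -
                                        pool(normalize_block(y, "zscore"), "tsd"))^2))
  expect_lte(dist_ab(A, C), dist_ab(A, B) + dist_ab(B, C) + 1e-12)
})

test_that("bilateral distances are invariant under a common entry permutation", {
  rec <- make_record(n_sources = 4, n_detectors = 2, T = 6, seed = 36)
  spec <- representation_spec(760, "zscore", "tsd")
  d0 <- build_bilateral(rec, spec)$values
  # permute channels identically on both sides (isometry of the part vectors)
  perm <- sample(8)
  rec2 <- rec
  for (k in c("left_760", "right_760"))
    rec2$blocks[[k]]$values <- rec2$blocks[[k]]$values[perm, ]
  expect_equal(build_bilateral(rec2, spec)$values, d0)
})
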