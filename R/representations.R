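#' Representation specifications
#'
#' A representation spec is one point in the pipeline's design space: a
#' wavelength set (760, 830, or both), a non-empty set of 1-3 normalization
#' methods, and one pooling method. A spec expands into `L = |wavelengths| *
#' |normalizations|` single-feature parts, concatenated (early fusion) in
#' canonical order: wavelength ascending outer, normalization in the fixed
#' order relative_change, zscore, zero_center, robust inner.
#'
#' @param wavelengths numeric subset of `c(760, 830)`, non-empty.
#' @param normalizations character subset of the four normalization methods,
#'   size 1 to `max_norms`.
#' @param pooling one of `"rf"`, `"tsd"`, `"ssd"`, `"tf"`, `"sf"`.
#' @param max_norms upper bound on the normalization subset size (default 3).
#' @return An object of class `representation_spec`.
#' @seealso [enumerate_specs()], [build_unilateral()], [build_bilateral()]
#' @export
representation_spec <- function(wavelengths, normalizations, pooling,
                                max_norms = 3L) {
  wavelengths <- sort(unique(as.numeric(wavelengths)))
  if (length(wavelengths) == 0 || !all(wavelengths %in% c(760, 830)))
    stop_validation("wavelengths must be a non-empty subset of {760, 830}")
  normalizations <- as.character(normalizations)
  if (!all(normalizations %in% norm_methods) ||
      anyDuplicated(normalizations) ||
      length(normalizations) < 1L || length(normalizations) > max_norms)
    stop_validation(sprintf(
      "normalizations must be 1..%d distinct methods from: %s",
      max_norms, paste(norm_methods, collapse = ", ")))
  # canonical inner order
  normalizations <- norm_methods[norm_methods %in% normalizations]
  pooling <- match.arg(tolower(pooling), pool_methods)
  structure(list(wavelengths = wavelengths, normalizations = normalizations,
                 pooling = pooling),
            class = "representation_spec")
}

#' @export
format.representation_spec <- function(x, ...) {
  norm_labels <- c(relative_change = "relative change", zscore = "Z-score",
                   zero_center = "zero-centering", robust = "robust")
  sprintf("A: %s nm; B: %s; C: %s",
          paste(x$wavelengths, collapse = ", "),
          paste(norm_labels[x$normalizations], collapse = " + "),
          toupper(x$pooling))
}

#' @export
print.representation_spec <- function(x, ...) {
  cat("<representation_spec> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Enumerate the representation design space
#'
#' Enumerates every representation spec exactly once in deterministic
#' lexicographic order: wavelength choice outer (760; 830; 760+830), then
#' normalization subsets ordered by size then by the fixed method order, then
#' pooling (rf, tsd, ssd, tf, sf). With the default bounds (normalization
#' subsets of sizes 1-3 out of 4) this yields 3 x 14 x 5 = 210 specs. The
#' size bounds are parameters so that other readings of the design space can
#' be explored.
#'
#' @param min_norms,max_norms bounds on the normalization subset size.
#' @return List of [representation_spec()]s.
#' @export
#' @examples
#' length(enumerate_specs())  # 210
enumerate_specs <- function(min_norms = 1L, max_norms = 3L) {
  wl_sets <- list(760, 830, c(760, 830))
  norm_sets <- list()
  for (k in seq(min_norms, max_norms)) {
    cmb <- utils::combn(norm_methods, k, simplify = FALSE)
    norm_sets <- c(norm_sets, cmb)
  }
  out <- list()
  for (wl in wl_sets)
    for (ns in norm_sets)
      for (pm in pool_methods)
        out[[length(out) + 1L]] <-
          representation_spec(wl, ns, pm, max_norms = max_norms)
  out
}

# parts of a spec in canonical order: list of (wavelength, normalization)
spec_parts <- function(spec) {
  parts <- list()
  for (wl in spec$wavelengths)
    for (nm in spec$normalizations)
      parts[[length(parts) + 1L]] <- list(wavelength_nm = wl, normalization = nm)
  parts
}

# length of one pooled part for a given block shape
part_length <- function(pooling, R, T) {
  switch(pooling, rf = R * T, tsd = R, ssd = T, tf = R + T, sf = 6L)
}

# pooled single-feature part for one side; cache is an environment or NULL
pooled_part <- function(record, side, wl, nm, pooling, cache = NULL) {
  key <- paste(record$subject_id, side, wl, nm, pooling, sep = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  block <- record$blocks[[block_key(side, wl)]]
  v <- tryCatch(
    pool(normalize_block(block, nm), pooling),
    bdot_degenerate_data = function(e) {
      stop_degenerate(sprintf("subject '%s', side %s, %g nm, %s: %s",
                              record$subject_id, side, wl, nm,
                              conditionMessage(e)))
    })
  if (!is.null(cache) && pooling != "rf") cache[[key]] <- v
  v
}

#' Build a unilateral representation
#'
#' Concatenates, in canonical part order, the pooled single-feature vectors
#' `pool(normalize(block), spec$pooling)` for every (wavelength,
#' normalization) pair of the spec — the early-fusion representation of one
#' breast.
#'
#' @param record a [subject_record()].
#' @param side `"left"` or `"right"`.
#' @param spec a [representation_spec()].
#' @param cache optional environment for memoizing pooled parts across specs.
#' @return A list of class `unilateral_representation` with elements `values`
#'   (numeric vector), `side`, `spec`, and `parts` (the provenance of each
#'   concatenated part).
#' @export
build_unilateral <- function(record, side, spec, cache = NULL) {
  stopifnot(inherits(record, "subject_record"),
            inherits(spec, "representation_spec"))
  side <- match.arg(side, c("left", "right"))
  parts <- spec_parts(spec)
  vecs <- lapply(parts, function(pp)
    pooled_part(record, side, pp$wavelength_nm, pp$normalization,
                spec$pooling, cache))
  structure(list(values = unlist(vecs, use.names = FALSE), side = side,
                 spec = spec, parts = parts),
            class = "unilateral_representation")
}

#' Build a bilateral distance representation
#'
#' For each single-feature part of the spec (canonical order), computes the
#' Euclidean distance between the right- and left-breast part vectors,
#' yielding one non-negative distance per part. This collapses the
#' high-dimensional unilateral representations into an `L`-vector sensitive
#' to between-breast asymmetry — the self-referencing that makes uncalibrated
#' bilateral scans comparable across subjects. Distances are accumulated
#' part-wise, so memory stays proportional to one block even for raw-feature
#' parts.
#'
#' @param record a [subject_record()].
#' @param spec a [representation_spec()].
#' @param cache optional environment for memoizing pooled parts.
#' @return A list of class `bilateral_vector` with elements `values`
#'   (length-`L` non-negative numeric) and `spec`.
#' @export
build_bilateral <- function(record, spec, cache = NULL) {
  stopifnot(inherits(record, "subject_record"),
            inherits(spec, "representation_spec"))
  parts <- spec_parts(spec)
  d <- vapply(parts, function(pp) {
    r <- pooled_part(record, "right", pp$wavelength_nm, pp$normalization,
                     spec$pooling, cache)
    l <- pooled_part(record, "left", pp$wavelength_nm, pp$normalization,
                     spec$pooling, cache)
    if (length(r) != length(l))
      stop_consistency("left/right part dimensions differ")
    sqrt(sum((r - l)^2))
  }, numeric(1))
  structure(list(values = d, spec = spec), class = "bilateral_vector")
}

#' Feature cache for repeated representation building
#'
#' Returns an environment that [build_unilateral()] and [build_bilateral()]
#' use to memoize pooled single-feature parts across the many specs examined
#' during model selection (raw-feature parts are never cached; they are
#' recomputed streamingly).
#'
#' @return An environment.
#' @export
feature_cache <- function() new.env(parent = emptyenv())
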