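#' Compare single- and multi-feature representations across wavelengths
#'
#' For each classification mode and each wavelength restriction, runs model
#' selection over the corresponding representation subsets and evaluates the
#' winner on the predefined test set. Single-feature candidates use one
#' wavelength and one normalization; multi-feature candidates are the full
#' enumeration whose wavelength sets fall inside the restriction. One split
#' plan per mode is reused across all restrictions, so differences between
#' rows reflect representations rather than split noise.
#'
#' @param cohort_ a [cohort()].
#' @param modes character subset of `c("unilateral", "bilateral")`.
#' @param wavelength_restrictions list of wavelength sets (default
#'   `list(760, 830, c(760, 830))`).
#' @param plan_seed seed for the split plans.
#' @param C_grid,n_splits,test_frac,val_frac forwarded to the selection
#'   machinery.
#' @return A data.frame with one row per (mode, restriction, representation
#'   class): the winning spec in `A: ...; B: ...; C: ...` notation, its mean
#'   validation AUC, and the test AUC.
#' @export
run_comparison <- function(cohort_, modes = c("unilateral", "bilateral"),
                           wavelength_restrictions = list(760, 830, c(760, 830)),
                           plan_seed = 1L, C_grid = default_C_grid(),
                           n_splits = 20L, test_frac = 0.2, val_frac = 0.2) {
  all_specs <- enumerate_specs()
  out <- list()
  for (mode in modes) {
    plan <- make_split_plan(cohort_, mode, test_frac, val_frac, n_splits,
                            seed = plan_seed)
    cache <- feature_cache()
    for (wl in wavelength_restrictions) {
      subsets <- list(
        single = Filter(function(s)
          length(s$wavelengths) == 1L && all(s$wavelengths %in% wl) &&
            length(s$normalizations) == 1L, all_specs),
        multi = Filter(function(s) all(s$wavelengths %in% wl), all_specs))
      for (cls in names(subsets)) {
        sel <- select_model(cohort_, subsets[[cls]], C_grid, plan, mode, cache)
        ev <- final_evaluate(cohort_, sel, plan, mode, cache)
        out[[length(out) + 1L]] <- data.frame(
          mode = mode,
          wavelengths = paste(wl, collapse = " & "),
          representation = cls,
          best_spec = format(sel$best_spec),
          best_C = sel$best_C,
          validation_auc = sel$validation_auc_mean,
          test_auc = ev$auc,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Sparse optode-grid ablation
#'
#' Re-runs the pipeline on channel subsets emulating instruments with fewer
#' sources and detectors: for each grid geometry and mode, all blocks are
#' restricted to the grid, the given representation is re-selected over the
#' cost grid with the same plan seed, and the test AUC recorded. Rows are
#' summarized per (grid size, mode) by median/min/max, the spread across
#' alternative arrangements of the same size.
#'
#' @param cohort_ a [cohort()].
#' @param grids list of [grid_geometry()] objects.
#' @param spec_uni,spec_bi the representation used in unilateral / bilateral
#'   mode (`NULL` skips that mode).
#' @param plan_seed seed shared by all split plans.
#' @param C_grid,n_splits,test_frac,val_frac forwarded to the selection
#'   machinery.
#' @return A list of class `ablation_report`: `rows` (data.frame per grid x
#'   mode) and `summaries` (median/min/max per grid size x mode).
#' @export
run_sparse_ablation <- function(cohort_, grids, spec_uni = NULL, spec_bi = NULL,
                                plan_seed = 1L, C_grid = default_C_grid(),
                                n_splits = 20L, test_frac = 0.2,
                                val_frac = 0.2) {
  stopifnot(length(grids) >= 1)
  modes <- c(if (!is.null(spec_uni)) "unilateral",
             if (!is.null(spec_bi)) "bilateral")
  if (length(modes) == 0) stop_validation("supply spec_uni and/or spec_bi")
  rows <- list()
  for (g in grids) {
    sub <- subset_cohort(cohort_, g)
    size_label <- sprintf("%dx%d", length(g$kept_sources),
                          length(g$kept_detectors))
    for (mode in modes) {
      spec <- if (mode == "unilateral") spec_uni else spec_bi
      plan <- make_split_plan(sub, mode, test_frac, val_frac, n_splits,
                              seed = plan_seed)
      sel <- select_model(sub, list(spec), C_grid, plan, mode)
      ev <- final_evaluate(sub, sel, plan, mode)
      rows[[length(rows) + 1L]] <- data.frame(
        grid_size = size_label, grid_name = g$name, mode = mode,
        auc = ev$auc, stringsAsFactors = FALSE)
    }
  }
  rows <- do.call(rbind, rows)
  agg <- stats::aggregate(auc ~ grid_size + mode, rows, function(v)
    c(median = stats::median(v), min = min(v), max = max(v)))
  summaries <- cbind(agg[c("grid_size", "mode")], as.data.frame(agg$auc))
  structure(list(rows = rows, summaries = summaries),
            class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  cat("<ablation_report>\n")
  print(x$summaries, row.names = FALSE)
  invisible(x)
}

#' Example sparse optode grids
#'
#' Generates evenly spaced source/detector subsets of a full grid, following
#' the curation principle that sparse layouts should cover the tissue
#' homogeneously without local clustering. For each requested size, variants
#' are produced by shifting the even spacing to different offsets, yielding
#' distinct arrangements of the same channel count (the first variant starts
#' at index 0, emulating co-located source/detector positions on instruments
#' where sources double as detectors; later variants are offset).
#'
#' @param sizes list of `c(n_sources, n_detectors)` pairs to generate.
#' @param n_variants number of offset variants per size.
#' @param n_sources,n_detectors dimensions of the full grid.
#' @return List of [grid_geometry()] objects.
#' @export
#' @examples
#' grids <- example_grids(sizes = list(c(16, 16)), n_variants = 2)
#' grids[[1]]
example_grids <- function(sizes = list(c(32, 32), c(16, 16), c(8, 8), c(4, 4)),
                          n_variants = 2L, n_sources = 32L, n_detectors = 64L) {
  even_pick <- function(k, n, offset) {
    idx <- floor(offset + (0:(k - 1)) * n / k)
    sort(unique(pmin(idx, n - 1L)))
  }
  out <- list()
  for (sz in sizes) {
    ks <- sz[1]; kd <- sz[2]
    stopifnot(ks <= n_sources, kd <= n_detectors)
    for (v in seq_len(n_variants)) {
      off_s <- (v - 1) * max(1, floor(n_sources / ks / 2)) %% max(1, n_sources / ks)
      off_d <- (v - 1) * max(1, floor(n_detectors / kd / 2)) %% max(1, n_detectors / kd)
      out[[length(out) + 1L]] <- grid_geometry(
        even_pick(ks, n_sources, off_s), even_pick(kd, n_detectors, off_d),
        name = sprintf("%dx%d/%s", ks, kd, letters[v]))
    }
  }
  out
}
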