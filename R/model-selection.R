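# units of analysis: breasts (unilateral) or patients (bilateral)
cohort_units <- function(cohort_, mode = c("unilateral", "bilateral")) {
  mode <- match.arg(mode)
  if (mode == "bilateral") {
    ids <- vapply(cohort_$records, function(r) r$subject_id, character(1))
    labels <- as.integer(vapply(cohort_$records,
                                function(r) r$cancer_positive, logical(1)))
  } else {
    ids <- character(0); labels <- integer(0)
    for (r in cohort_$records) {
      for (side in c("left", "right")) {
        ids <- c(ids, paste(r$subject_id, side, sep = "_"))
        labels <- c(labels, as.integer(r$tumor_side == side))
      }
    }
  }
  list(ids = ids, labels = labels)
}

# stratified draw of floor(frac * n) units: per-stratum floor allocation,
# remainder to the largest fractional parts (ties by stratum order)
stratified_take <- function(ids, labels, frac) {
  n_take <- floor(frac * length(ids))
  strata <- split(seq_along(ids), labels)
  exact <- vapply(strata, length, integer(1)) * frac
  base <- floor(exact)
  rem <- n_take - sum(base)
  if (rem > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  taken <- integer(0)
  for (s in seq_along(strata)) {
    k <- base[s]
    if (k > length(strata[[s]]))
      stop_stratification(sprintf(
        "stratum '%s' has %d units, %d required",
        names(strata)[s], length(strata[[s]]), k))
    if (k > 0) taken <- c(taken, sample(strata[[s]], k))
  }
  sort(taken)
}

#' Build the model-selection / test split plan
#'
#' Splits the cohort's analysis units — individual breasts in unilateral
#' mode (left and right breasts of one patient may land in different
#' subsets), patients in bilateral mode — into a disjoint model-selection
#' set and a single predefined test set, then draws repeated overlapping
#' stratified shuffle splits of the model-selection set into training and
#' validation. Held-out sizes use the floor rule `floor(frac * n)`; draws
#' are stratified by label. For a 63-subject cohort with the default
#' fractions this yields 126 breasts split 101/25 with 81/20 shuffle splits
#' (unilateral), and 63 patients split 51/12 with 41/10 (bilateral).
#'
#' @param cohort_ a [cohort()].
#' @param mode `"unilateral"` or `"bilateral"`.
#' @param test_frac fraction of units held out for the final test (default
#'   0.2).
#' @param val_frac fraction of model-selection units held out for validation
#'   in each shuffle split (default 0.2).
#' @param n_splits number of shuffle splits (default 20).
#' @param seed integer seed for all draws.
#' @return An object of class `split_plan` with fields `unit_ids`, `labels`,
#'   `model_selection_ids`, `test_ids`, `shuffle_splits` (list of
#'   `list(train, validation)` id vectors), `mode`, `seed`.
#' @export
make_split_plan <- function(cohort_, mode = c("unilateral", "bilateral"),
                            test_frac = 0.2, val_frac = 0.2,
                            n_splits = 20L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(test_frac > 0, test_frac < 1, val_frac > 0, val_frac < 1,
            n_splits >= 1)
  u <- cohort_units(cohort_, mode)
  with_seed(seed, {
    test_idx <- stratified_take(u$ids, u$labels, test_frac)
    ms_idx <- setdiff(seq_along(u$ids), test_idx)
    ms_ids <- u$ids[ms_idx]
    ms_labels <- u$labels[ms_idx]
    splits <- lapply(seq_len(n_splits), function(k) {
      val <- stratified_take(ms_ids, ms_labels, val_frac)
      list(train = ms_ids[setdiff(seq_along(ms_ids), val)],
           validation = ms_ids[val])
    })
    structure(list(unit_ids = u$ids, labels = u$labels,
                   model_selection_ids = ms_ids,
                   test_ids = u$ids[test_idx],
                   shuffle_splits = splits, mode = mode,
                   seed = as.integer(seed)),
              class = "split_plan")
  })
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %s: %d units -> %d model-selection / %d test; %d shuffle splits (%d train / %d validation)\n",
              x$mode, length(x$unit_ids), length(x$model_selection_ids),
              length(x$test_ids), length(x$shuffle_splits),
              length(x$shuffle_splits[[1]]$train),
              length(x$shuffle_splits[[1]]$validation)))
  invisible(x)
}

#' Feature matrix for one representation spec
#'
#' Builds the design matrix for all analysis units of a cohort under one
#' representation spec: one row per breast (unilateral) or per patient
#' (bilateral distance vector).
#'
#' @param cohort_ a [cohort()].
#' @param spec a [representation_spec()].
#' @param mode `"unilateral"` or `"bilateral"`.
#' @param cache optional [feature_cache()].
#' @return List with `x` (matrix, rownames = unit ids), `labels` (0/1
#'   integer), `unit_ids`.
#' @export
feature_matrix <- function(cohort_, spec, mode = c("unilateral", "bilateral"),
                           cache = NULL) {
  mode <- match.arg(mode)
  u <- cohort_units(cohort_, mode)
  rows <- if (mode == "bilateral") {
    lapply(cohort_$records, function(r) build_bilateral(r, spec, cache)$values)
  } else {
    unlist(lapply(cohort_$records, function(r) list(
      build_unilateral(r, "left", spec, cache)$values,
      build_unilateral(r, "right", spec, cache)$values)),
      recursive = FALSE)
  }
  x <- do.call(rbind, rows)
  rownames(x) <- u$ids
  list(x = x, labels = u$labels, unit_ids = u$ids)
}

#' Train a linear maximum-margin classifier
#'
#' Fits a linear support vector machine (hinge loss, inverse regularization
#' `C`) and returns a scorer whose decision values are higher for more
#' cancer-like inputs. Features enter with no per-column standardization —
#' relative scaling is the job of the block normalizations under study. For
#' numerical conditioning only, the whole training matrix is divided by a
#' single global scale factor (the root-mean-square of its entries) before
#' the solver runs; a scalar rescaling preserves all relative feature scales
#' and only re-anchors the dimensionless cost grid, but keeps the
#' optimization well-conditioned across representations whose raw magnitudes
#' differ by orders of magnitude. Training is deterministic given the
#' samples and `C`.
#'
#' @param x numeric feature matrix, one row per sample.
#' @param y binary labels (0/1), both classes present.
#' @param C positive cost parameter.
#' @return An object of class `linear_scorer`; use [predict.linear_scorer()]
#'   to obtain decision scores.
#' @export
train_linear_classifier <- function(x, y, C = 1) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop_degenerate_training("training data contain a single class")
  if (nrow(unique(x)) == 1L)
    stop_degenerate_training("all training feature vectors are identical")
  if (C <= 0) stop_validation("C must be positive")
  gscale <- sqrt(mean(x^2))
  if (gscale == 0) gscale <- 1
  fit <- e1071::svm(x / gscale, factor(y, levels = c(0L, 1L)),
                    kernel = "linear", cost = C, scale = FALSE)
  # libsvm's decision-value sign favors the class named first in the
  # decision-value column label; orient so higher score = class 1
  dv <- attr(stats::predict(fit, x[1, , drop = FALSE] / gscale,
                            decision.values = TRUE),
             "decision.values")
  flip <- !startsWith(colnames(dv)[1], "1")
  structure(list(fit = fit, flip = flip, C = C, gscale = gscale),
            class = "linear_scorer")
}

#' @param object a `linear_scorer`.
#' @param newdata numeric matrix of feature vectors.
#' @param ... unused.
#' @rdname train_linear_classifier
#' @export
predict.linear_scorer <- function(object, newdata, ...) {
  dv <- attr(stats::predict(object$fit, as.matrix(newdata) / object$gscale,
                            decision.values = TRUE),
             "decision.values")
  s <- as.numeric(dv[, 1])
  if (object$flip) -s else s
}

#' @export
coef.linear_scorer <- function(object, ...) {
  w <- drop(crossprod(object$fit$coefs, object$fit$SV)) / object$gscale
  b <- -object$fit$rho
  if (object$flip) { w <- -w; b <- -b }
  c(`(intercept)` = b, w)
}

default_C_grid <- function() 10^seq(-3, 3, length.out = 7)

#' Select a representation and SVM cost by cross-validated AUC
#'
#' For every (spec, C) candidate, builds the feature design, trains a linear
#' SVM on each shuffle split's training units, scores its validation units,
#' and records the mean validation AUC over splits. All candidates share the
#' same split plan, so differences reflect the representations, not split
#' noise. The winner maximizes mean validation AUC; ties break by smaller
#' total feature dimension, then candidate order, then smaller `C`.
#'
#' @param cohort_ a [cohort()].
#' @param candidate_specs list of [representation_spec()]s.
#' @param C_grid positive cost values (default 7 values log-spaced
#'   `1e-3 ... 1e3`).
#' @param plan a [make_split_plan()] consistent with `cohort_` and `mode`.
#' @param mode `"unilateral"` or `"bilateral"`.
#' @param cache optional [feature_cache()] shared across calls.
#' @return An object of class `selection_result` with the best spec/C, its
#'   validation AUC mean/sd, and the full per-candidate table.
#' @export
select_model <- function(cohort_, candidate_specs, C_grid = default_C_grid(),
                         plan, mode = c("unilateral", "bilateral"),
                         cache = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(plan, "split_plan"), plan$mode == mode,
            length(candidate_specs) >= 1, all(C_grid > 0))
  if (is.null(cache)) cache <- feature_cache()

  rows <- vector("list", length(candidate_specs) * length(C_grid))
  k <- 0L
  for (si in seq_along(candidate_specs)) {
    spec <- candidate_specs[[si]]
    fm <- feature_matrix(cohort_, spec, mode, cache)
    names(fm$labels) <- fm$unit_ids
    for (C in C_grid) {
      aucs <- vapply(seq_along(plan$shuffle_splits), function(j) {
        sp <- plan$shuffle_splits[[j]]
        scorer <- tryCatch(
          train_linear_classifier(fm$x[sp$train, , drop = FALSE],
                                  fm$labels[sp$train], C),
          bdot_degenerate_training = function(e) stop_degenerate_training(
            sprintf("spec %d ('%s'), split %d: %s", si,
                    format(spec), j, conditionMessage(e))))
        scores <- predict(scorer, fm$x[sp$validation, , drop = FALSE])
        roc_auc(scores, fm$labels[sp$validation])$auc
      }, numeric(1))
      k <- k + 1L
      rows[[k]] <- data.frame(
        spec_index = si, spec_label = format(spec), C = C,
        mean_val_auc = mean(aucs), sd_val_auc = stats::sd(aucs),
        dim = ncol(fm$x), stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab$mean_val_auc, tab$dim, tab$spec_index, tab$C)
  best <- tab[ord[1], ]
  structure(list(
    best_spec = candidate_specs[[best$spec_index]],
    best_C = best$C,
    validation_auc_mean = best$mean_val_auc,
    validation_auc_sd = best$sd_val_auc,
    per_spec_table = tab, mode = mode),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s\n  best: %s (C = %g), validation AUC %.3f +/- %.3f over %d candidates\n",
              x$mode, format(x$best_spec), x$best_C, x$validation_auc_mean,
              x$validation_auc_sd, nrow(x$per_spec_table)))
  invisible(x)
}

#' Final evaluation on the predefined test set
#'
#' Retrains the selected (spec, C) on all model-selection units and scores
#' the test units once, returning their ROC curve and AUC. A single
#' predefined test set (rather than nested folds) keeps the evaluation
#' strictly disjoint from every selection decision.
#'
#' @param cohort_ a [cohort()].
#' @param result a [select_model()] result (or any list with `best_spec`,
#'   `best_C`).
#' @param plan the same [make_split_plan()] used for selection.
#' @param mode `"unilateral"` or `"bilateral"`.
#' @param cache optional [feature_cache()].
#' @return List of class `final_evaluation`: `roc` ([roc_auc()] result),
#'   `auc`, `scores`, `test_labels`, `scorer`.
#' @export
final_evaluate <- function(cohort_, result, plan,
                           mode = c("unilateral", "bilateral"), cache = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(plan, "split_plan"), plan$mode == mode)
  fm <- feature_matrix(cohort_, result$best_spec, mode, cache)
  names(fm$labels) <- fm$unit_ids
  scorer <- train_linear_classifier(
    fm$x[plan$model_selection_ids, , drop = FALSE],
    fm$labels[plan$model_selection_ids], result$best_C)
  scores <- predict(scorer, fm$x[plan$test_ids, , drop = FALSE])
  names(scores) <- plan$test_ids
  roc <- roc_auc(scores, fm$labels[plan$test_ids])
  structure(list(roc = roc, auc = roc$auc, scores = scores,
                 test_labels = fm$labels[plan$test_ids], scorer = scorer),
            class = "final_evaluation")
}

#' @export
print.final_evaluation <- function(x, ...) {
  cat(sprintf("<final_evaluation> test AUC %.3f (%d positive / %d negative test units)\n",
              x$auc, x$roc$n_pos, x$roc$n_neg))
  invisible(x)
}
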