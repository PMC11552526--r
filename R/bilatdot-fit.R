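#' Fit a bilateral/unilateral optical-mammography classifier
#'
#' The package's main entry point: given a cohort of bilateral
#' transillumination scans, this runs the full analysis — enumerate candidate
#' data representations, split the units into model-selection and test sets,
#' select the representation and SVM cost by cross-validated AUC over
#' stratified shuffle splits, retrain the winner on all model-selection
#' units, and evaluate it once on the predefined test set.
#'
#' @param cohort_ a [cohort()], e.g. from [generate_cohort()] or
#'   [load_cohort()].
#' @param mode `"bilateral"` (classify patients from between-breast feature
#'   distances) or `"unilateral"` (classify each breast independently).
#' @param specs list of candidate [representation_spec()]s; default the full
#'   210-spec enumeration.
#' @param C_grid positive SVM cost values to search.
#' @param test_frac,val_frac,n_splits split protocol parameters (defaults
#'   0.2 / 0.2 / 20).
#' @param seed integer seed for the split plan.
#' @return An object of class `bilatdot` with `print`, `summary`, `coef`,
#'   `predict` and `plot` methods. Fields include `selection` (the
#'   [select_model()] result), `evaluation` (test-set ROC/AUC), `plan`, and
#'   the retrained `scorer`.
#' @export
#' @examples
#' co <- generate_cohort(sim_params(n_subjects = 16, n_sources = 4,
#'                                  n_detectors = 8, n_frames = 48, seed = 3))
#' fit <- bilatdot(co, mode = "bilateral",
#'                 specs = list(representation_spec(760, "zscore", "sf")),
#'                 n_splits = 5, seed = 3)
#' fit
bilatdot <- function(cohort_, mode = c("bilateral", "unilateral"),
                     specs = enumerate_specs(), C_grid = default_C_grid(),
                     test_frac = 0.2, val_frac = 0.2, n_splits = 20L,
                     seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort_, "cohort"))
  plan <- make_split_plan(cohort_, mode, test_frac, val_frac, n_splits, seed)
  cache <- feature_cache()
  selection <- select_model(cohort_, specs, C_grid, plan, mode, cache)
  evaluation <- final_evaluate(cohort_, selection, plan, mode, cache)
  structure(list(
    mode = mode, plan = plan, selection = selection,
    evaluation = evaluation, scorer = evaluation$scorer,
    n_subjects = length(cohort_$records),
    call = match.call()),
    class = "bilatdot")
}

#' @export
print.bilatdot <- function(x, ...) {
  cat("Bilateral diffuse optical transillumination classifier\n\n")
  cat(sprintf("  mode:            %s (%d subjects, %d units)\n", x$mode,
              x$n_subjects, length(x$plan$unit_ids)))
  cat(sprintf("  representation:  %s\n", format(x$selection$best_spec)))
  cat(sprintf("  SVM cost C:      %g\n", x$selection$best_C))
  cat(sprintf("  validation AUC:  %.3f +/- %.3f (%d shuffle splits)\n",
              x$selection$validation_auc_mean, x$selection$validation_auc_sd,
              length(x$plan$shuffle_splits)))
  cat(sprintf("  test AUC:        %.3f (%d pos / %d neg test units)\n",
              x$evaluation$auc, x$evaluation$roc$n_pos,
              x$evaluation$roc$n_neg))
  invisible(x)
}

#' @export
summary.bilatdot <- function(object, n_top = 10L, ...) {
  tab <- object$selection$per_spec_table
  best_per_spec <- tab[order(-tab$mean_val_auc), ]
  best_per_spec <- best_per_spec[!duplicated(best_per_spec$spec_index), ]
  structure(list(fit = object,
                 top = utils::head(best_per_spec, n_top)),
            class = "summary.bilatdot")
}

#' @export
print.summary.bilatdot <- function(x, ...) {
  print(x$fit)
  cat("\nTop candidate representations (best C per spec, by validation AUC):\n")
  tab <- x$top[, c("spec_label", "C", "mean_val_auc", "sd_val_auc", "dim")]
  rownames(tab) <- NULL
  print(tab, digits = 3)
  invisible(x)
}

#' @export
coef.bilatdot <- function(object, ...) coef(object$scorer)

#' Score new subjects with a fitted classifier
#'
#' Applies the selected representation and the retrained SVM to new data.
#' In bilateral mode, returns one decision score per subject; in unilateral
#' mode, one per breast. Higher scores are more cancer-like.
#'
#' @param object a fitted [bilatdot()] model.
#' @param newdata a [cohort()] or list of [subject_record()]s with the same
#'   block dimensions as the training cohort.
#' @param ... unused.
#' @return Named numeric vector of decision scores.
#' @export
predict.bilatdot <- function(object, newdata, ...) {
  if (inherits(newdata, "subject_record")) newdata <- list(newdata)
  if (!inherits(newdata, "cohort"))
    newdata <- cohort(newdata)
  fm <- feature_matrix(newdata, object$selection$best_spec, object$mode)
  s <- predict(object$scorer, fm$x)
  names(s) <- fm$unit_ids
  s
}

#' @export
plot.bilatdot <- function(x, ...) {
  plot(x$evaluation$roc,
       main = sprintf("%s, test AUC = %.1f%%", format(x$selection$best_spec),
                      100 * x$evaluation$auc), ...)
  invisible(x)
}
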