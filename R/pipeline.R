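#' Run the end-to-end analysis from a configuration
#'
#' Orchestrates simulate/load -> select -> evaluate (-> ablate) and writes
#' all artifacts to a self-describing run directory: the resolved
#' configuration, a manifest, the per-candidate selection table, test-set
#' ROC points and AUC, and (if configured) the ablation table. Identical
#' configurations produce identical artifacts.
#'
#' The configuration is a named list (or a path to a YAML/JSON file parsed
#' into one) with fields:
#' * `simulation`: arguments for [sim_params()] (must include `seed`), or
#'   `cohort_path`: an existing cohort container directory (exactly one of
#'   the two);
#' * `mode`: `"bilateral"` or `"unilateral"`;
#' * `specs`: `"all"` for the full enumeration, or a list of lists with
#'   `wavelengths` / `normalizations` / `pooling`;
#' * `c_grid` (optional), `n_splits`, `test_frac`, `val_frac`;
#' * `plan_seed`: integer seed for the split plan (required);
#' * `ablation` (optional): list with `sizes` (list of two-element vectors)
#'   and `n_variants` for [example_grids()].
#'
#' @param config named list or path to a YAML/JSON config file.
#' @param out_dir directory to write artifacts into (created if needed).
#' @return The run directory path, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop_validation("reading YAML configs requires the 'yaml' package")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort_ <- if (!is.null(cfg$cohort_path)) {
    load_cohort(cfg$cohort_path)
  } else {
    generate_cohort(do.call(sim_params, cfg$simulation))
  }

  specs <- if (identical(cfg$specs, "all")) enumerate_specs() else
    lapply(cfg$specs, function(s)
      representation_spec(s$wavelengths, s$normalizations, s$pooling))

  fit <- bilatdot(cohort_, mode = cfg$mode, specs = specs,
                  C_grid = cfg$c_grid, test_frac = cfg$test_frac,
                  val_frac = cfg$val_frac, n_splits = cfg$n_splits,
                  seed = cfg$plan_seed)

  wj <- function(x, f) jsonlite::write_json(
    x, file.path(out_dir, f), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  wj(config, "config.json")
  wj(list(package = "bilatdot",
          version = as.character(utils::packageVersion("bilatdot")),
          mode = cfg$mode, n_subjects = length(cohort_$records)),
     "run_manifest.json")
  data.table::fwrite(fit$selection$per_spec_table,
                     file.path(out_dir, "selection_table.csv"))
  wj(list(best_spec = format(fit$selection$best_spec),
          best_C = fit$selection$best_C,
          validation_auc_mean = fit$selection$validation_auc_mean,
          validation_auc_sd = fit$selection$validation_auc_sd,
          test_auc = fit$evaluation$auc),
     "results.json")
  data.table::fwrite(fit$evaluation$roc$points,
                     file.path(out_dir, "roc_points.csv"))

  if (!is.null(cfg$ablation)) {
    b1 <- cohort_$records[[1]]$blocks[[1]]
    grids <- example_grids(
      sizes = cfg$ablation$sizes,
      n_variants = cfg$ablation$n_variants %||% 2L,
      n_sources = b1$n_sources, n_detectors = b1$n_detectors)
    rep_ <- run_sparse_ablation(
      cohort_, grids,
      spec_uni = if (cfg$mode == "unilateral") fit$selection$best_spec,
      spec_bi = if (cfg$mode == "bilateral") fit$selection$best_spec,
      plan_seed = cfg$plan_seed, C_grid = cfg$c_grid,
      n_splits = cfg$n_splits, test_frac = cfg$test_frac,
      val_frac = cfg$val_frac)
    data.table::fwrite(rep_$rows, file.path(out_dir, "ablation_rows.csv"))
    data.table::fwrite(rep_$summaries,
                       file.path(out_dir, "ablation_summaries.csv"))
  }
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_config <- function(config) {
  if (!is.list(config)) stop_validation("config must be a named list")
  has_sim <- !is.null(config$simulation)
  has_path <- !is.null(config$cohort_path)
  if (has_sim == has_path)
    stop_validation("config needs exactly one of 'simulation' or 'cohort_path'")
  if (has_sim && is.null(config$simulation$seed))
    stop_validation("config field 'simulation' must include a 'seed'")
  if (is.null(config$plan_seed))
    stop_validation("config is missing required seed field 'plan_seed'")
  list(
    simulation = config$simulation,
    cohort_path = config$cohort_path,
    mode = match.arg(config$mode %||% "bilateral",
                     c("bilateral", "unilateral")),
    specs = config$specs %||% "all",
    c_grid = config$c_grid %||% default_C_grid(),
    n_splits = as.integer(config$n_splits %||% 20L),
    test_frac = config$test_frac %||% 0.2,
    val_frac = config$val_frac %||% 0.2,
    plan_seed = as.integer(config$plan_seed),
    ablation = config$ablation)
}
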