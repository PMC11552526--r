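test_that("roc_auc matches hand-computed examples", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(c(0.9, 0.3, 0.8, 0.2), c(1, 1, 0, 0))$auc, 0.75)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_error(roc_auc(c(1, 2), c(1, 1)), class = "bdot_undefined_auc")
})

test_that("ROC points run from (0,0) to (1,1) monotonically", {
  set.seed(71)
  r <- roc_auc(rnorm(40), rep(c(0, 1), 20))
  expect_equal(unlist(r$points[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$points[nrow(r$points), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
})

test_that("trapezoidal area equals Mann-Whitney pair counting on random cases", {
  set.seed(72)
  for (rep in 1:1000) {
    n <- sample(4:30, 1)
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    # duplicate some scores to exercise tie handling
    scores <- sample(round(rnorm(n), sample(c(1, 8), 1)))
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, bf_trapezoid(r$points), tolerance = 1e-12)
    expect_equal(r$auc, bf_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(73)
  for (rep in 1:25) {
    n <- sample(10:40, 1)
    labels <- c(0, 1, sample(c(0, 1), n - 2, replace = TRUE))
    scores <- round(rnorm(n), 1)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(74)
  scores <- rnorm(30); labels <- rep(c(0, 1), 15)
  a0 <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, a0)
  expect_equal(roc_auc(3 * scores + 7, labels)$auc, a0)
  # complement symmetry
  expect_equal(roc_auc(-scores, labels)$auc, 1 - a0)
})

test_that("the comparison runner respects wavelength restrictions", {
  co <- generate_cohort(sim_params(n_subjects = 14, prevalence = 0.5,
                                   n_sources = 3, n_detectors = 4,
                                   n_frames = 32, seed = 75))
  tab <- run_comparison(co, modes = "bilateral",
                        wavelength_restrictions = list(760),
                        plan_seed = 2, C_grid = 1, n_splits = 3)
  expect_identical(nrow(tab), 2L)
  expect_true(all(grepl("^A: 760 nm", tab$best_spec)))
  expect_setequal(tab$representation, c("single", "multi"))
  expect_true(all(tab$test_auc >= 0 & tab$test_auc <= 1))
})

test_that("ablation with the identity grid reproduces the full-grid result", {
  co <- generate_cohort(sim_params(n_subjects = 14, prevalence = 0.5,
                                   n_sources = 4, n_detectors = 4,
                                   n_frames = 32, seed = 76))
  spec <- representation_spec(760, "relative_change", "sf")
  full <- grid_geometry(0:3, 0:3, name = "full")
  half <- grid_geometry(c(0, 2), c(0, 2), name = "2x2/a")
  rep_ <- run_sparse_ablation(co, list(full, half), spec_bi = spec,
                              plan_seed = 4, C_grid = 1, n_splits = 3)
  expect_identical(nrow(rep_$rows), 2L)

  plan <- make_split_plan(co, "bilateral", n_splits = 3, seed = 4)
  sel <- select_model(co, list(spec), 1, plan, "bilateral")
  ev <- final_evaluate(co, sel, plan, "bilateral")
  expect_equal(rep_$rows$auc[rep_$rows$grid_name == "full"], ev$auc)
  expect_true(all(rep_$rows$auc >= 0 & rep_$rows$auc <= 1))
})

test_that("ablation summaries aggregate rows by median/min/max", {
  co <- generate_cohort(sim_params(n_subjects = 12, prevalence = 0.5,
                                   n_sources = 4, n_detectors = 4,
                                   n_frames = 32, seed = 77))
  spec <- representation_spec(760, "zscore", "sf")
  grids <- list(grid_geometry(c(0, 1), c(0, 1), "2x2/a"),
                grid_geometry(c(2, 3), c(2, 3), "2x2/b"),
                grid_geometry(c(0, 2), c(1, 3), "2x2/c"))
  rep_ <- run_sparse_ablation(co, grids, spec_bi = spec, plan_seed = 5,
                              C_grid = 1, n_splits = 3)
  expect_identical(unique(rep_$rows$grid_size), "2x2")
  sm <- rep_$summaries
  expect_equal(sm$median, median(rep_$rows$auc))
  expect_equal(sm$min, min(rep_$rows$auc))
  expect_equal(sm$max, max(rep_$rows$auc))
})

test_that("example_grids produce valid, distinct geometries", {
  grids <- example_grids(sizes = list(c(16, 16), c(8, 8)), n_variants = 2)
  expect_length(grids, 4)
  for (g in grids) {
    expect_s3_class(g, "grid_geometry")
    expect_true(all(diff(g$kept_sources) > 0))
    expect_true(all(g$kept_detectors >= 0 & g$kept_detectors < 64))
  }
  expect_false(identical(grids[[1]]$kept_detectors, grids[[2]]$kept_detectors))
})
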