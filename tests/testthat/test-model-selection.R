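# a 63-subject cohort at tiny block size for split arithmetic tests
tiny63 <- function(seed = 51) {
  records <- lapply(1:63, function(i)
    make_record(sprintf("P%02d", i), n_sources = 2, n_detectors = 2, T = 4,
                tumor_side = if (i <= 18) c("left", "right")[1 + i %% 2] else "none",
                seed = seed + i))
  cohort(records)
}

test_that("split arithmetic reproduces the canonical counts for N = 63", {
  co <- tiny63()
  pu <- make_split_plan(co, "unilateral", seed = 1)
  expect_length(pu$unit_ids, 126)
  expect_length(pu$model_selection_ids, 101)
  expect_length(pu$test_ids, 25)
  expect_length(pu$shuffle_splits, 20)
  expect_length(pu$shuffle_splits[[1]]$train, 81)
  expect_length(pu$shuffle_splits[[1]]$validation, 20)

  pb <- make_split_plan(co, "bilateral", seed = 1)
  expect_length(pb$unit_ids, 63)
  expect_length(pb$test_ids, 12)
  expect_length(pb$model_selection_ids, 51)
  expect_length(pb$shuffle_splits[[1]]$train, 41)
  expect_length(pb$shuffle_splits[[1]]$validation, 10)
})

test_that("splits are disjoint, covering, and stratified within one unit", {
  co <- tiny63()
  for (mode in c("unilateral", "bilateral")) {
    p <- make_split_plan(co, mode, seed = 3)
    expect_length(intersect(p$model_selection_ids, p$test_ids), 0)
    expect_setequal(c(p$model_selection_ids, p$test_ids), p$unit_ids)
    lab <- setNames(p$labels, p$unit_ids)
    overall <- mean(lab)
    n_test_pos <- sum(lab[p$test_ids])
    expect_lte(abs(n_test_pos - overall * length(p$test_ids)), 1)
    for (sp in p$shuffle_splits) {
      expect_length(intersect(sp$train, sp$validation), 0)
      expect_setequal(c(sp$train, sp$validation), p$model_selection_ids)
      n_val_pos <- sum(lab[sp$validation])
      expect_lte(abs(n_val_pos - mean(lab[p$model_selection_ids]) *
                       length(sp$validation)), 1)
    }
  }
})

test_that("split plans are deterministic in the seed and differ across seeds", {
  co <- tiny63()
  expect_identical(make_split_plan(co, "bilateral", seed = 7),
                   make_split_plan(co, "bilateral", seed = 7))
  expect_false(identical(make_split_plan(co, "bilateral", seed = 7)$test_ids,
                         make_split_plan(co, "bilateral", seed = 8)$test_ids))
})

test_that("the linear classifier separates a separable toy problem", {
  x <- rbind(c(0, 0), c(0.2, 0), c(1, 1), c(0.8, 1))
  y <- c(0, 0, 1, 1)
  sc <- train_linear_classifier(x, y, C = 1)
  s <- predict(sc, x)
  expect_gt(min(s[y == 1]), max(s[y == 0]))
  expect_equal(roc_auc(s, y)$auc, 1.0)
  # linear weights recover the separating direction
  w <- coef(sc)
  expect_true(all(w[-1] > 0))
})

test_that("regularization C -> 0 pulls contradictory duplicates toward majority", {
  # same point duplicated with 3 positive and 1 negative labels, plus anchors
  x <- rbind(c(1, 0), c(1, 0), c(1, 0), c(1, 0), c(0, 0), c(2, 0))
  y <- c(1, 1, 1, 0, 0, 1)
  sc <- train_linear_classifier(x, y, C = 1e-4)
  s <- predict(sc, x)
  # the majority-positive duplicated point scores above the negative anchor
  expect_gt(s[1], s[5])
})

test_that("degenerate training inputs raise classed errors", {
  expect_error(train_linear_classifier(diag(3), c(1, 1, 1), 1),
               class = "bdot_degenerate_training")
  expect_error(
    train_linear_classifier(matrix(1, 4, 2), c(0, 1, 0, 1), 1),
    class = "bdot_degenerate_training")
})

test_that("training and scoring are deterministic", {
  set.seed(61)
  x <- matrix(rnorm(60), 20, 3)
  y <- rep(c(0, 1), 10)
  s1 <- predict(train_linear_classifier(x, y, 1), x)
  s2 <- predict(train_linear_classifier(x, y, 1), x)
  expect_identical(s1, s2)
})

test_that("select_model returns the trivial candidate and a full table", {
  co <- make_cohort(n = 14, n_sources = 3, n_detectors = 2, T = 8, n_pos = 6,
                    seed = 62)
  plan <- make_split_plan(co, "bilateral", n_splits = 4, seed = 5)
  spec <- representation_spec(760, "zscore", "sf")
  sel <- select_model(co, list(spec), C_grid = 1, plan = plan,
                      mode = "bilateral")
  expect_identical(format(sel$best_spec), format(spec))
  expect_identical(sel$best_C, 1)
  expect_identical(nrow(sel$per_spec_table), 1L)
  expect_gte(sel$validation_auc_mean, 0)
  expect_lte(sel$validation_auc_mean, 1)
})

test_that("selection is invariant to candidate order up to the tie-break", {
  co <- make_cohort(n = 14, n_sources = 3, n_detectors = 2, T = 8, n_pos = 6,
                    seed = 63)
  plan <- make_split_plan(co, "bilateral", n_splits = 4, seed = 6)
  specs <- list(representation_spec(760, "zscore", "sf"),
                representation_spec(830, "relative_change", "tsd"),
                representation_spec(760, "robust", "ssd"))
  s1 <- select_model(co, specs, C_grid = c(0.1, 10), plan = plan, mode = "bilateral")
  s2 <- select_model(co, rev(specs), C_grid = c(0.1, 10), plan = plan, mode = "bilateral")
  expect_identical(format(s1$best_spec), format(s2$best_spec))
  expect_identical(s1$best_C, s2$best_C)
  expect_equal(s1$validation_auc_mean, s2$validation_auc_mean)
})

test_that("end-to-end selection and evaluation are deterministic", {
  co <- generate_cohort(sim_params(n_subjects = 16, prevalence = 0.5,
                                   n_sources = 3, n_detectors = 4,
                                   n_frames = 32, seed = 64))
  plan <- make_split_plan(co, "bilateral", n_splits = 4, seed = 9)
  specs <- list(representation_spec(760, "relative_change", "sf"))
  s1 <- select_model(co, specs, c(0.1, 1), plan, "bilateral")
  s2 <- select_model(co, specs, c(0.1, 1), plan, "bilateral")
  expect_equal(s1, s2)
  e1 <- final_evaluate(co, s1, plan, "bilateral")
  e2 <- final_evaluate(co, s2, plan, "bilateral")
  expect_equal(e1$roc, e2$roc)
  expect_identical(e1$auc, e2$auc)
})

test_that("final_evaluate trains on model-selection units only", {
  co <- generate_cohort(sim_params(n_subjects = 16, prevalence = 0.5,
                                   n_sources = 3, n_detectors = 4,
                                   n_frames = 32, seed = 65))
  plan <- make_split_plan(co, "bilateral", n_splits = 4, seed = 10)
  spec <- representation_spec(760, "relative_change", "sf")
  sel <- select_model(co, list(spec), 1, plan, "bilateral")
  ev <- final_evaluate(co, sel, plan, "bilateral")
  expect_identical(names(ev$scores), plan$test_ids)
  expect_identical(ev$roc$n_pos + ev$roc$n_neg, length(plan$test_ids))
})
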