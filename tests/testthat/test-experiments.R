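# End-to-end experiment orchestration on small centroid-model scenarios.

plan_batches <- function(seed = 21, n = 500, drift_delta = 0) {
  b <- generate_batches(drift_scenario(n_train = n, n_test = 200, n_score = 400,
                                       d = 10, active_fraction = 0.25,
                                       drift_delta = drift_delta, seed = seed))
  plan <- make_split_plan(b$train$y, k_folds = 5L, n_icps = 3L, seed = seed)
  list(b = b, plan = plan)
}

test_that("split plans stratify, partition, and round-trip through JSON", {
  y <- rep(c(0L, 1L), c(90, 10))
  plan <- make_split_plan(y, k_folds = 5L, n_icps = 2L, seed = 4)
  expect_equal(as.vector(table(plan$fold_assignments)), rep(20L, 5))
  for (f in 1:5) expect_equal(sum(y[plan$fold_assignments == f]), 2L)
  # per-fold ICP splits partition the fold's training portion
  for (f in 1:5) {
    tr <- which(plan$fold_assignments != f)
    for (sp in plan$icp_splits[[f]])
      expect_equal(sort(c(sp$prop, sp$cal)), tr)
  }
  path <- file.path(tempdir(), "plan.json")
  write_split_plan(plan, path)
  expect_identical(read_split_plan(path), plan)
  unlink(path)
  expect_error(make_split_plan(rep(c(0L, 1L), c(98, 2)), k_folds = 5L),
               "at least 5")
})

test_that("internal CV is valid at the headline level on exchangeable data", {
  pb <- plan_batches(seed = 22, n = 600)
  e1 <- exp1_internal_cv(pb$b$train$x, pb$b$train$y, pb$plan, centroid_spec())
  expect_length(e1$fold_curves, 5L)
  err <- mean(e1$summary$error_overall)
  n_fold <- length(pb$b$train$y) / 5
  expect_lte(err, 0.2 + 3 * sqrt(0.2 * 0.8 / n_fold))
  expect_s3_class(e1$fold_curves[[1]], "calibration_curve")
})

test_that("external prediction without drift stays valid, with drift it breaks", {
  pb0 <- plan_batches(seed = 23, n = 600, drift_delta = 0)
  e1 <- exp1_internal_cv(pb0$b$train$x, pb0$b$train$y, pb0$plan, centroid_spec())
  e2 <- exp2_predict_external(e1, pb0$b$score$x, pb0$b$score$y)
  n <- length(pb0$b$score$y)
  expect_lte(mean(e2$summary$error_overall), 0.2 + 3 * sqrt(0.2 * 0.8 / n))

  pb3 <- plan_batches(seed = 23, n = 600, drift_delta = 3)
  e1d <- exp1_internal_cv(pb3$b$train$x, pb3$b$train$y, pb3$plan, centroid_spec())
  e2d <- exp2_predict_external(e1d, pb3$b$score$x, pb3$b$score$y)
  expect_gt(mean(e2d$summary$error_overall), 0.2 + 3 * sqrt(0.2 * 0.8 / n))
  # identical external set across folds: five curves from five fold models
  expect_length(e2d$fold_curves, 5L)
  expect_error(exp2_predict_external(e1, pb0$b$score$x[, 1:3], pb0$b$score$y),
               "dimension")
})

test_that("the SCP experiment shares the plan's fold training compounds", {
  pb <- plan_batches(seed = 24)
  e3 <- exp3_scp(pb$b$train$x, pb$b$train$y, pb$plan,
                 pb$b$score$x, pb$b$score$y, spec = centroid_spec())
  expect_length(e3$fold_curves, 5L)
  for (f in 1:5)
    expect_equal(e3$models[[f]]$train_index, which(pb$plan$fold_assignments != f))
})

test_that("training-set update pools the update batch into each fold", {
  pb <- plan_batches(seed = 25)
  e4 <- exp4_train_update(pb$b$train$x, pb$b$train$y, pb$plan,
                          pb$b$test$x, pb$b$test$y,
                          pb$b$score$x, pb$b$score$y, spec = centroid_spec())
  f1 <- e4$models[[1]]
  n_expected <- sum(pb$plan$fold_assignments != 1) + length(pb$b$test$y)
  expect_equal(length(f1$splits[[1]]$prop) + length(f1$splits[[1]]$cal), n_expected)
})

test_that("calibration update keeps fitted models byte-identical", {
  pb <- plan_batches(seed = 26)
  e1 <- exp1_internal_cv(pb$b$train$x, pb$b$train$y, pb$plan, centroid_spec())
  e5 <- exp5_cal_update(e1, pb$b$test$x, pb$b$test$y, pb$b$score$x, pb$b$score$y)
  for (f in seq_along(e1$models))
    for (i in seq_along(e1$models[[f]]$icps))
      expect_identical(e5$models[[f]]$icps[[i]]$model, e1$models[[f]]$icps[[i]]$model)
  # every ICP now calibrates on the whole new batch
  expect_equal(sum(e5$models[[1]]$icps[[1]]$sizes), length(pb$b$test$y))
})

test_that("the half-and-half update splits the external batch disjointly", {
  pb <- plan_batches(seed = 27)
  e1 <- exp1_internal_cv(pb$b$train$x, pb$b$train$y, pb$plan, centroid_spec())
  e6 <- exp6_cal_update_half(e1, pb$b$score$x, pb$b$score$y, seed = 27)
  y <- pb$b$score$y
  for (h in e6$halves) {
    expect_length(intersect(h$prop, h$cal), 0)
    expect_equal(sort(c(h$prop, h$cal)), seq_along(y))
    expect_lte(abs(sum(y[h$cal]) - sum(y[h$prop])), 1)  # stratified halves
  }
})

test_that("recalibration restores validity under drift and lowers the RMSD", {
  pb <- plan_batches(seed = 28, n = 600, drift_delta = 3)
  e1 <- exp1_internal_cv(pb$b$train$x, pb$b$train$y, pb$plan, centroid_spec())
  e2 <- exp2_predict_external(e1, pb$b$score$x, pb$b$score$y)
  e5 <- exp5_cal_update(e1, pb$b$test$x, pb$b$test$y, pb$b$score$x, pb$b$score$y)
  e6 <- exp6_cal_update_half(e1, pb$b$score$x, pb$b$score$y, seed = 28)
  r2 <- summarise_experiment(e2)$rmsd_overall
  expect_gt(r2, summarise_experiment(e5)$rmsd_overall)
  expect_gt(r2, summarise_experiment(e6)$rmsd_overall)
})

test_that("experiment archives round-trip through the versioned loader", {
  pb <- plan_batches(seed = 29, n = 300)
  pb$plan <- make_split_plan(pb$b$train$y, k_folds = 5L, n_icps = 2L, seed = 29)
  e1 <- exp1_internal_cv(pb$b$train$x, pb$b$train$y, pb$plan, centroid_spec())
  f <- file.path(tempdir(), "exp1.rds")
  save_experiment(e1, f)
  e1b <- load_experiment(f)
  expect_equal(e1b$summary, e1$summary)
  expect_equal(e1b$fold_curves, e1$fold_curves)
  saveRDS(list(format = "other"), f)
  expect_error(load_experiment(f), "not a cpdrift experiment archive")
  unlink(f)
})
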