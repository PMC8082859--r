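# Orchestration of the six drift/recalibration experiments over shared,
# persisted cross-validation splits:
#   1 internal CV of an ACP on the training batch
#   2 the CV models predict an external (later) batch
#   3 SCP on the same fold training sets predicts the external batch
#   4 training-set update: fold training data + update batch, refit, predict
#   5 calibration-set update: keep fitted models, recalibrate on the update
#     batch, predict
#   6 calibration-set update with half of the external batch, predict the
#     other half
# The headline reporting significance level is 0.2; full-grid curves are
# always stored.

#' Build (and optionally persist) a shared cross-validation split plan
#'
#' Stratified k-fold assignment plus, per fold, the per-ICP stratified
#' proper/calibration splits of the fold's training portion. Persisting the
#' plan and reusing it across experiments guarantees that every experiment
#' sees identical per-fold training compounds, so results are directly
#' comparable.
#'
#' @param y 0/1 label vector of the training batch.
#' @param k_folds Number of CV folds (default 5).
#' @param n_icps ICPs per ACP (default 20).
#' @param cal_fraction Calibration fraction of each ICP split (default 0.3).
#' @param seed Integer seed.
#' @param path Optional file; when given the plan is written there as JSON.
#' @return An object of class \code{split_plan}.
#' @export
make_split_plan <- function(y, k_folds = 5L, n_icps = 20L, cal_fraction = 0.3,
                            seed = 1L, path = NULL) {
  y <- as.integer(y)
  folds <- stratified_folds(y, k = k_folds, seed = seed)
  icp_splits <- lapply(seq_len(k_folds), function(f) {
    tr <- which(folds != f)
    lapply(seq_len(n_icps), function(i) {
      sp <- stratified_split(y[tr], cal_fraction, seed = .seed_mix(seed, 3L, f, i))
      list(prop = tr[sp$prop], cal = tr[sp$cal])
    })
  })
  plan <- structure(list(fold_assignments = folds, icp_splits = icp_splits,
                         k_folds = as.integer(k_folds), n_icps = as.integer(n_icps),
                         cal_fraction = cal_fraction, seed = as.integer(seed)),
                    class = "split_plan")
  if (!is.null(path)) write_split_plan(plan, path)
  plan
}

#' @rdname make_split_plan
#' @param plan A \code{split_plan}.
#' @export
write_split_plan <- function(plan, path) {
  stopifnot(inherits(plan, "split_plan"))
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname make_split_plan
#' @export
read_split_plan <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  plan <- list(
    fold_assignments = as.integer(raw$fold_assignments),
    icp_splits = lapply(raw$icp_splits, function(fold)
      lapply(fold, function(sp) list(prop = as.integer(sp$prop), cal = as.integer(sp$cal)))),
    k_folds = as.integer(raw$k_folds), n_icps = as.integer(raw$n_icps),
    cal_fraction = raw$cal_fraction, seed = as.integer(raw$seed))
  class(plan) <- "split_plan"
  plan
}

# Assemble the per-experiment result container.
experiment_result <- function(id, name, fold_pvals, fold_labels, models,
                              grid, epsilon, config) {
  curves <- mapply(function(pv, lab) calibration_curve(pv, lab, grid),
                   fold_pvals, fold_labels, SIMPLIFY = FALSE)
  rmsd <- lapply(curves, rmsd_calibration)
  headline <- do.call(rbind, mapply(function(pv, lab, f) {
    sets <- prediction_set(pv$p0, pv$p1, epsilon)
    er <- error_rate(sets, lab, by_class = TRUE)
    ef <- efficiency(sets, lab, by_class = TRUE)
    data.frame(fold = f, epsilon = epsilon,
               error_overall = er[["overall"]], error_0 = er[["class0"]],
               error_1 = er[["class1"]],
               efficiency_overall = ef[["overall"]], efficiency_0 = ef[["class0"]],
               efficiency_1 = ef[["class1"]])
  }, fold_pvals, fold_labels, seq_along(fold_pvals), SIMPLIFY = FALSE))
  structure(list(experiment_id = id, name = name, fold_curves = curves,
                 fold_rmsd = rmsd, summary = headline, fold_pvals = fold_pvals,
                 fold_labels = fold_labels, models = models, config = config),
            class = "experiment_result")
}

#' Mean RMSD and headline error/efficiency of an experiment
#'
#' @param result An \code{experiment_result}.
#' @return One-row data frame with fold-averaged overall/per-class RMSD and
#'   the error and efficiency at the headline significance level.
#' @export
summarise_experiment <- function(result) {
  stopifnot(inherits(result, "experiment_result"))
  r <- function(k) mean(vapply(result$fold_rmsd, function(x) x[[k]], numeric(1)), na.rm = TRUE)
  data.frame(experiment_id = result$experiment_id, name = result$name,
             rmsd_overall = r("overall"), rmsd_actives = r("actives"),
             rmsd_inactives = r("inactives"),
             error = mean(result$summary$error_overall, na.rm = TRUE),
             efficiency = mean(result$summary$efficiency_overall, na.rm = TRUE))
}

default_grid <- function() seq(0, 1, by = 0.1)

#' Experiment 1: internal cross-validation of an ACP on the training batch
#'
#' Per fold, an ACP is fitted on the other folds' data using the plan's
#' persisted per-ICP splits and evaluated on the held-out fold.
#'
#' @param x,y Training batch features and 0/1 labels; the plan must have been
#'   built on \code{y}.
#' @param plan A \code{\link{make_split_plan}} object.
#' @param spec A \code{\link{score_model_spec}}.
#' @param grid Significance grid for the stored curves.
#' @param epsilon Headline significance level (default 0.2).
#' @return An \code{experiment_result} whose \code{models} are the per-fold
#'   ACPs (reused by experiments 2, 5 and 6).
#' @export
exp1_internal_cv <- function(x, y, plan, spec = score_model_spec(),
                             grid = default_grid(), epsilon = 0.2) {
  stopifnot(inherits(plan, "split_plan"), length(y) == length(plan$fold_assignments))
  x <- as.matrix(x); y <- as.integer(y)
  folds <- plan$fold_assignments
  fits <- lapply(seq_len(plan$k_folds), function(f)
    acp_fit(x, y, spec = spec, seed = plan$seed + f, splits = plan$icp_splits[[f]]))
  pvals <- lapply(seq_len(plan$k_folds), function(f)
    acp_predict(fits[[f]], x[folds == f, , drop = FALSE]))
  labels <- lapply(seq_len(plan$k_folds), function(f) y[folds == f])
  experiment_result(1L, "internal_cv", pvals, labels, fits, grid, epsilon,
                    list(plan_seed = plan$seed, spec = spec, grid = grid, epsilon = epsilon))
}

#' Experiment 2: predict an external batch with the CV models
#'
#' Each fold's ACP from experiment 1 predicts the full external batch; no
#' refitting. Systematic excess of observed error over the significance
#' level across folds is the drift diagnostic.
#'
#' @param exp1 The \code{experiment_result} of \code{\link{exp1_internal_cv}}.
#' @param x_ext,y_ext External batch features and labels.
#' @inheritParams exp1_internal_cv
#' @export
exp2_predict_external <- function(exp1, x_ext, y_ext,
                                  grid = default_grid(), epsilon = 0.2) {
  stopifnot(inherits(exp1, "experiment_result"), exp1$experiment_id == 1L)
  x_ext <- as.matrix(x_ext); y_ext <- as.integer(y_ext)
  pvals <- lapply(exp1$models, acp_predict, x = x_ext)
  labels <- rep(list(y_ext), length(exp1$models))
  experiment_result(2L, "pred_external", pvals, labels, exp1$models, grid, epsilon,
                    c(exp1$config, list(n_external = length(y_ext))))
}

#' Experiment 3: SCP on the shared fold training sets
#'
#' Per fold, a synergy conformal predictor (fixed stratified calibration
#' set, k equal proper-training partitions, averaged nonconformities) is
#' fitted on exactly the fold training compounds of the shared plan and
#' predicts the external batch.
#'
#' @inheritParams exp1_internal_cv
#' @param x_ext,y_ext External batch features and labels.
#' @param k Number of SCP partitions (default 4).
#' @export
exp3_scp <- function(x, y, plan, x_ext, y_ext, k = 4L,
                     spec = score_model_spec(), grid = default_grid(), epsilon = 0.2) {
  stopifnot(inherits(plan, "split_plan"))
  x <- as.matrix(x); y <- as.integer(y)
  x_ext <- as.matrix(x_ext); y_ext <- as.integer(y_ext)
  folds <- plan$fold_assignments
  fits <- lapply(seq_len(plan$k_folds), function(f) {
    tr <- which(folds != f)
    scp <- scp_fit(x[tr, , drop = FALSE], y[tr], k = k,
                   cal_fraction = plan$cal_fraction, spec = spec,
                   seed = plan$seed + f)
    scp$train_index <- tr
    scp
  })
  pvals <- lapply(fits, scp_predict, x = x_ext)
  labels <- rep(list(y_ext), length(fits))
  experiment_result(3L, "pred_external_scp", pvals, labels, fits, grid, epsilon,
                    list(plan_seed = plan$seed, k = k, spec = spec,
                         grid = grid, epsilon = epsilon))
}

#' Experiment 4: update the training set and retrain
#'
#' Per fold, the fold's training portion is pooled with the update batch,
#' fresh stratified 70/30 ACP splits are drawn, a new ACP is fitted, and the
#' external batch is predicted.
#'
#' @inheritParams exp3_scp
#' @param x_upd,y_upd Update batch (disjoint from the external batch).
#' @export
exp4_train_update <- function(x, y, plan, x_upd, y_upd, x_ext, y_ext,
                              spec = score_model_spec(), grid = default_grid(),
                              epsilon = 0.2) {
  stopifnot(inherits(plan, "split_plan"))
  x <- as.matrix(x); y <- as.integer(y)
  x_upd <- as.matrix(x_upd); y_upd <- as.integer(y_upd)
  x_ext <- as.matrix(x_ext); y_ext <- as.integer(y_ext)
  folds <- plan$fold_assignments
  fits <- lapply(seq_len(plan$k_folds), function(f) {
    tr <- which(folds != f)
    acp_fit(rbind(x[tr, , drop = FALSE], x_upd), c(y[tr], y_upd),
            n_models = plan$n_icps, cal_fraction = plan$cal_fraction,
            spec = spec, seed = .seed_mix(plan$seed, 4L, f))
  })
  pvals <- lapply(fits, acp_predict, x = x_ext)
  labels <- rep(list(y_ext), length(fits))
  experiment_result(4L, "train_update", pvals, labels, fits, grid, epsilon,
                    list(plan_seed = plan$seed, n_update = length(y_upd),
                         spec = spec, grid = grid, epsilon = epsilon))
}

#' Experiment 5: update only the calibration set
#'
#' Every ICP in every fold's ACP from experiment 1 keeps its fitted score
#' model; its calibration nonconformity scores are recomputed on the entire
#' new calibration batch. The external batch is then predicted.
#'
#' @inheritParams exp2_predict_external
#' @param x_cal,y_cal New calibration batch (e.g. the intermediate release).
#' @export
exp5_cal_update <- function(exp1, x_cal, y_cal, x_ext, y_ext,
                            grid = default_grid(), epsilon = 0.2) {
  stopifnot(inherits(exp1, "experiment_result"), exp1$experiment_id == 1L)
  x_ext <- as.matrix(x_ext); y_ext <- as.integer(y_ext)
  fits <- lapply(exp1$models, acp_recalibrate, x_cal = x_cal, y_cal = y_cal)
  pvals <- lapply(fits, acp_predict, x = x_ext)
  labels <- rep(list(y_ext), length(fits))
  experiment_result(5L, "cal_update", pvals, labels, fits, grid, epsilon,
                    c(exp1$config, list(n_new_cal = length(y_cal))))
}

#' Experiment 6: recalibrate on half of the external batch, predict the rest
#'
#' Per fold, the external batch is split 50/50 randomly stratified; one half
#' replaces the calibration set of the fold's (unrefitted) ACP, the other
#' half is predicted. Calibration and test data are then exchangeable by
#' construction, so validity should be restored.
#'
#' @inheritParams exp2_predict_external
#' @param seed Seed for the per-fold 50/50 external splits.
#' @export
exp6_cal_update_half <- function(exp1, x_ext, y_ext, seed = 1L,
                                 grid = default_grid(), epsilon = 0.2) {
  stopifnot(inherits(exp1, "experiment_result"), exp1$experiment_id == 1L)
  x_ext <- as.matrix(x_ext); y_ext <- as.integer(y_ext)
  if (any(table(factor(y_ext, levels = c(0L, 1L))) < 2L))
    stop("each class needs at least 2 external examples for a stratified half split")
  halves <- lapply(seq_along(exp1$models), function(f)
    stratified_split(y_ext, cal_fraction = 0.5, seed = .seed_mix(seed, 6L, f)))
  fits <- mapply(function(acp, h)
    acp_recalibrate(acp, x_ext[h$cal, , drop = FALSE], y_ext[h$cal]),
    exp1$models, halves, SIMPLIFY = FALSE)
  pvals <- mapply(function(acp, h)
    acp_predict(acp, x_ext[h$prop, , drop = FALSE]),
    fits, halves, SIMPLIFY = FALSE)
  labels <- lapply(halves, function(h) y_ext[h$prop])
  res <- experiment_result(6L, "cal_update_half", pvals, labels, fits, grid, epsilon,
                           c(exp1$config, list(half_seed = seed)))
  res$halves <- halves
  res
}

#' Persist / reload experiment models and results
#'
#' Versioned archive (RDS-based) so that downstream experiments can reuse
#' the CV models of experiment 1 across sessions.
#'
#' @param result An \code{experiment_result}.
#' @param path Archive file path.
#' @export
save_experiment <- function(result, path) {
  stopifnot(inherits(result, "experiment_result"))
  saveRDS(list(format = "cpdrift-experiment", version = 1L, result = result), path)
  invisible(path)
}

#' @rdname save_experiment
#' @export
load_experiment <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "cpdrift-experiment"))
    stop("not a cpdrift experiment archive: ", path)
  if (obj$version > 1L) stop("archive version ", obj$version, " is newer than this package")
  obj$result
}
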