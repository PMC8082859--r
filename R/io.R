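#' Assemble a run configuration
#'
#' A fully serialisable record of everything that determines a run's
#' numbers: endpoint, model hyperparameters, conformal set-up, grid and
#' seeds. Every result directory gets the resolved configuration written
#' next to the numbers, so any result on disk is reproducible from
#' (config + inputs).
#'
#' @param endpoint Endpoint name.
#' @param spec A \code{\link{score_model_spec}}.
#' @param n_icps,cal_fraction,k_folds,scp_partitions Conformal set-up.
#' @param grid Significance grid.
#' @param epsilon Headline significance level.
#' @param seed Master seed.
#' @param extra Named list of additional fields to record.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(endpoint = "synthetic", spec = score_model_spec(),
                       n_icps = 20L, cal_fraction = 0.3, k_folds = 5L,
                       scp_partitions = 4L, grid = seq(0, 1, 0.1),
                       epsilon = 0.2, seed = 1L, extra = list()) {
  structure(c(list(endpoint = endpoint,
                   algorithm = spec$algorithm, C = spec$C, gamma = spec$gamma,
                   n_icps = as.integer(n_icps), cal_fraction = cal_fraction,
                   k_folds = as.integer(k_folds),
                   scp_partitions = as.integer(scp_partitions),
                   grid = grid, epsilon = epsilon, seed = as.integer(seed)),
              extra),
            class = "run_config")
}

#' @rdname run_config
#' @param config A \code{run_config}.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- "run_config"
  cfg
}

#' Write an experiment's result tables
#'
#' Deterministic CSV serialisation of an \code{experiment_result}: the
#' per-fold calibration/efficiency curves (columns \code{fold},
#' \code{epsilon}, \code{class}, \code{error_rate}, \code{efficiency},
#' \code{n}), the per-fold RMSD summaries, the headline
#' error/efficiency-at-epsilon summary, and the resolved run configuration.
#'
#' @param result An \code{experiment_result}.
#' @param dir Output directory (created if needed).
#' @param config Optional \code{\link{run_config}} to write alongside.
#' @return \code{dir}, invisibly.
#' @export
write_results <- function(result, dir, config = NULL) {
  stopifnot(inherits(result, "experiment_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tag <- sprintf("exp%d_%s", result$experiment_id, result$name)
  curves <- do.call(rbind, lapply(seq_along(result$fold_curves), function(f)
    cbind(fold = f, as.data.frame(result$fold_curves[[f]]))))
  utils::write.csv(curves, file.path(dir, paste0(tag, "_curves.csv")), row.names = FALSE)
  rmsd <- do.call(rbind, lapply(seq_along(result$fold_rmsd), function(f)
    data.frame(fold = f,
               rmsd_overall = result$fold_rmsd[[f]]$overall,
               rmsd_actives = result$fold_rmsd[[f]]$actives,
               rmsd_inactives = result$fold_rmsd[[f]]$inactives)))
  utils::write.csv(rmsd, file.path(dir, paste0(tag, "_rmsd.csv")), row.names = FALSE)
  utils::write.csv(result$summary, file.path(dir, paste0(tag, "_summary.csv")),
                   row.names = FALSE)
  if (!is.null(config)) write_run_config(config, file.path(dir, paste0(tag, "_config.yaml")))
  invisible(dir)
}

#' Read back the curve table written by \code{\link{write_results}}
#'
#' @param dir Result directory.
#' @param experiment_id,name Identify the file (as written).
#' @return List with \code{curves}, \code{rmsd} and \code{summary} data
#'   frames.
#' @export
read_results <- function(dir, experiment_id, name) {
  tag <- sprintf("exp%d_%s", experiment_id, name)
  list(curves = utils::read.csv(file.path(dir, paste0(tag, "_curves.csv"))),
       rmsd = utils::read.csv(file.path(dir, paste0(tag, "_rmsd.csv"))),
       summary = utils::read.csv(file.path(dir, paste0(tag, "_summary.csv"))))
}
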