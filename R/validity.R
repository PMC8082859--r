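#' Monte-Carlo marginal-validity suite
#'
#' Fits replicate conformal predictors (ICP, ACP, SCP) on the training batch
#' of an exchangeable scenario, predicts the test batch with each, and
#' compares the replicate-mean per-class observed error at every grid
#' significance level against \code{epsilon + 3 * SE}. Averaging over
#' replicates mirrors how fold-mean error rates are reported in
#' cross-validated calibration plots; the standard error of that measured
#' mean has two binomial components — the test-set draw
#' (\code{eps(1-eps)/n_class}) and the calibration-rank noise shared by all
#' predictions of a replicate (\code{eps(1-eps)/n_cal_class}, averaged over
#' the \code{n_replicates} independent calibration draws) — combined in
#' quadrature.
#'
#' @param batches Output of \code{\link{generate_batches}} (train fitted,
#'   test evaluated).
#' @param spec A \code{\link{score_model_spec}}.
#' @param methods Subset of \code{c("icp", "acp", "scp")}.
#' @param n_replicates Replicate predictors per method (default 5).
#' @param n_models ICPs per ACP (default 20).
#' @param k SCP partitions (default 4).
#' @param cal_fraction Calibration fraction (default 0.3).
#' @param grid Significance levels checked (default 0.1..0.9).
#' @param seed Integer seed.
#' @return Data frame with columns \code{method}, \code{epsilon},
#'   \code{class}, \code{error} (replicate mean), \code{bound}
#'   (\code{epsilon + 3 * SE}) and \code{ok}.
#' @export
validity_mc <- function(batches, spec = score_model_spec(),
                        methods = c("icp", "acp", "scp"),
                        n_replicates = 5L, n_models = 20L, k = 4L,
                        cal_fraction = 0.3, grid = seq(0.1, 0.9, by = 0.1),
                        seed = 1L) {
  x <- batches$train$x; y <- batches$train$y
  xt <- batches$test$x; yt <- batches$test$y
  n_cls <- c(`0` = sum(yt == 0L), `1` = sum(yt == 1L))
  out <- list()
  for (method in methods) {
    pvs <- vector("list", n_replicates)
    n_cal <- matrix(0, n_replicates, 2, dimnames = list(NULL, c("0", "1")))
    for (r in seq_len(n_replicates)) {
      s <- .seed_mix(seed, 7L, match(method, c("icp", "acp", "scp")), r)
      if (method == "icp") {
        sp <- stratified_split(y, cal_fraction, seed = s)
        fit <- fit_icp(x[sp$prop, , drop = FALSE], y[sp$prop],
                       x[sp$cal, , drop = FALSE], y[sp$cal],
                       spec = spec, seed = s)
        pvs[[r]] <- predict_icp(fit, xt)
        n_cal[r, ] <- fit$sizes
      } else if (method == "acp") {
        fit <- acp_fit(x, y, n_models = n_models, cal_fraction = cal_fraction,
                       spec = spec, seed = s)
        pvs[[r]] <- acp_predict(fit, xt)
        n_cal[r, ] <- fit$icps[[1]]$sizes
      } else {
        fit <- scp_fit(x, y, k = k, cal_fraction = cal_fraction,
                       spec = spec, seed = s)
        pvs[[r]] <- scp_predict(fit, xt)
        n_cal[r, ] <- vapply(fit$cal_nc_avg, length, integer(1))
      }
    }
    for (eps in grid) {
      ers <- vapply(pvs, function(pv)
        error_rate(prediction_set(pv$p0, pv$p1, eps), yt, by_class = TRUE),
        numeric(3))
      for (cls in c("0", "1")) {
        err <- mean(ers[paste0("class", cls), ])
        se <- sqrt(eps * (1 - eps) *
                     (1 / n_cls[[cls]] + 1 / (n_replicates * mean(n_cal[, cls]))))
        out[[length(out) + 1]] <- data.frame(
          method = method, epsilon = eps, class = cls,
          error = err, bound = eps + 3 * se, ok = err <= eps + 3 * se)
      }
    }
  }
  do.call(rbind, out)
}
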