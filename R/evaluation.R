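#' Observed error rate of prediction sets
#'
#' The error rate is the fraction of examples whose prediction set excludes
#' the true label (1 minus the validity). The per-class rates restrict to
#' examples of that true label; a class with no examples yields \code{NA},
#' never 0.
#'
#' @param sets A \code{\link{prediction_set}} data frame (columns
#'   \code{in0}, \code{in1}).
#' @param labels True 0/1 labels, same length.
#' @param by_class If \code{TRUE}, return \code{c(overall, class0, class1)}.
#' @return A single rate, or a named vector when \code{by_class}.
#' @export
error_rate <- function(sets, labels, by_class = FALSE) {
  labels <- as.integer(labels)
  stopifnot(nrow(sets) == length(labels))
  miss <- ifelse(labels == 1L, !sets$in1, !sets$in0)
  rate <- function(v) if (length(v) == 0L) NA_real_ else mean(v)
  if (!by_class) return(rate(miss))
  c(overall = rate(miss),
    class0 = rate(miss[labels == 0L]),
    class1 = rate(miss[labels == 1L]))
}

#' Efficiency: fraction of single-label prediction sets
#'
#' Only \{0\} and \{1\} are informative prediction sets; empty and \{0,1\}
#' sets are not. Per-class efficiency restricts to examples of that true
#' label.
#'
#' @inheritParams error_rate
#' @return A single rate, or a named vector when \code{by_class}.
#' @export
efficiency <- function(sets, labels, by_class = FALSE) {
  labels <- as.integer(labels)
  stopifnot(nrow(sets) == length(labels))
  single <- xor(sets$in0, sets$in1)
  rate <- function(v) if (length(v) == 0L) NA_real_ else mean(v)
  if (!by_class) return(rate(single))
  c(overall = rate(single),
    class0 = rate(single[labels == 0L]),
    class1 = rate(single[labels == 1L]))
}

#' Calibration-and-efficiency curve
#'
#' Recomputes prediction sets at every grid significance level from the same
#' p-values and evaluates the observed error rate and efficiency, overall and
#' per class. The observed error of a conformal predictor should track the
#' diagonal; systematic excess signals broken exchangeability (data drift) or
#' small-sample resolution limits.
#'
#' @param pvals Data frame with columns \code{p0}, \code{p1}.
#' @param labels True 0/1 labels.
#' @param grid Strictly increasing significance levels (default
#'   \code{seq(0, 1, 0.1)}).
#' @return A data frame of class \code{calibration_curve} with columns
#'   \code{epsilon}, \code{class} (\code{"overall"}, \code{"0"}, \code{"1"}),
#'   \code{error_rate}, \code{efficiency}, \code{n}.
#' @export
calibration_curve <- function(pvals, labels, grid = seq(0, 1, by = 0.1)) {
  labels <- as.integer(labels)
  stopifnot(nrow(pvals) == length(labels), !is.unsorted(grid, strictly = TRUE))
  n_all <- length(labels); n0 <- sum(labels == 0L); n1 <- sum(labels == 1L)
  rows <- lapply(grid, function(eps) {
    sets <- prediction_set(pvals$p0, pvals$p1, eps)
    er <- error_rate(sets, labels, by_class = TRUE)
    ef <- efficiency(sets, labels, by_class = TRUE)
    data.frame(epsilon = eps,
               class = c("overall", "0", "1"),
               error_rate = unname(er),
               efficiency = unname(ef),
               n = c(n_all, n0, n1))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("calibration_curve", "data.frame")
  out
}

#' RMSD calibration summary
#'
#' Root-mean-square deviation between the observed error rate and the
#' significance level over the curve's grid, per class and overall; 0 means
#' perfect calibration.
#'
#' @param curve A \code{\link{calibration_curve}}.
#' @return Named list with elements \code{overall}, \code{actives} (class 1)
#'   and \code{inactives} (class 0), each in \code{[0, 1]}.
#' @export
rmsd_calibration <- function(curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  one <- function(cls) {
    sub <- curve[curve$class == cls, ]
    dev <- sub$error_rate - sub$epsilon
    if (all(is.na(dev))) return(NA_real_)
    if (anyNA(dev)) warning("grid points with no evaluable examples excluded from RMSD")
    sqrt(mean(dev^2, na.rm = TRUE))
  }
  list(overall = one("overall"), actives = one("1"), inactives = one("0"))
}

#' Plot a calibration-and-efficiency plot (CEP)
#'
#' Given per-fold calibration curves, draws the per-class mean observed error
#' (dark) and mean efficiency (light) against the significance level, with a
#' shaded band of +/- one standard deviation across folds and the diagonal
#' as the perfect-calibration reference.
#'
#' @param curves A list of \code{\link{calibration_curve}}s (one per fold).
#' @param out_path Output file; written via \code{ggplot2::ggsave}, so the
#'   extension selects the device (png, svg, pdf, ...).
#' @param title Optional plot title.
#' @return The ggplot object, invisibly; the file is created as a side
#'   effect.
#' @export
plot_cep <- function(curves, out_path = NULL, title = NULL) {
  if (inherits(curves, "calibration_curve")) curves <- list(curves)
  agg <- cep_fold_stats(curves)
  agg <- agg[agg$class %in% c("0", "1"), ]
  long <- rbind(
    data.frame(epsilon = agg$epsilon, class = agg$class, metric = "error rate",
               mean = agg$error_mean, sd = agg$error_sd),
    data.frame(epsilon = agg$epsilon, class = agg$class, metric = "efficiency",
               mean = agg$efficiency_mean, sd = agg$efficiency_sd))
  long$series <- interaction(long$metric, long$class, sep = " / class ")
  pal <- c("error rate / class 0" = "#00441b", "error rate / class 1" = "#67000d",
           "efficiency / class 0" = "#74c476", "efficiency / class 1" = "#fb6a4a")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$epsilon, y = .data$mean,
                                          colour = .data$series, fill = .data$series)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                                      ymax = pmin(.data$mean + .data$sd, 1)),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = pal, name = NULL) +
    ggplot2::scale_fill_manual(values = pal, name = NULL) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "significance level", y = "observed rate", title = title) +
    ggplot2::theme_minimal()
  if (!is.null(out_path)) ggplot2::ggsave(out_path, p, width = 5, height = 4, dpi = 150)
  invisible(p)
}

#' Pointwise fold statistics behind a CEP
#'
#' @param curves List of per-fold \code{\link{calibration_curve}}s sharing a
#'   grid.
#' @return Data frame with per (epsilon, class) mean and sd of error rate and
#'   efficiency across folds.
#' @export
cep_fold_stats <- function(curves) {
  stopifnot(length(curves) >= 1L)
  key <- curves[[1]][, c("epsilon", "class")]
  for (cv in curves)
    stopifnot(identical(cv[, c("epsilon", "class")], key))
  err <- vapply(curves, `[[`, numeric(nrow(key)), "error_rate")
  eff <- vapply(curves, `[[`, numeric(nrow(key)), "efficiency")
  err <- matrix(err, nrow = nrow(key)); eff <- matrix(eff, nrow = nrow(key))
  sd0 <- function(m) if (ncol(m) == 1L) rep(0, nrow(m)) else apply(m, 1, stats::sd)
  data.frame(key,
             error_mean = rowMeans(err), error_sd = sd0(err),
             efficiency_mean = rowMeans(eff), efficiency_sd = sd0(eff))
}
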