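#' Margin nonconformity score
#'
#' For per-class scores \eqn{(s_0, s_1)} summing to one and a hypothesised
#' label \eqn{y}, the margin nonconformity is
#' \deqn{nc = 0.5 - (s_y - s_{1-y}) / 2,}
#' which lies in \code{[0, 1]}: 0 when the model is maximally confident in
#' \eqn{y}, 1 when maximally confident in the other class, 0.5 at
#' indifference.
#'
#' @param scores An \code{n x 2} matrix of per-class scores (columns
#'   \code{"0"}, \code{"1"}), each row summing to 1 within \code{1e-6}.
#' @param label A single hypothesised label (0 or 1) or a vector of length
#'   \code{n} of true labels.
#' @return Numeric vector of nonconformity scores in \code{[0, 1]}.
#' @export
margin_nc <- function(scores, label) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2L) stop("scores must have two columns")
  if (any(abs(rowSums(scores) - 1) > 1e-6))
    stop("per-class scores must sum to 1 (tolerance 1e-6)")
  label <- as.integer(label)
  if (length(label) == 1L) label <- rep(label, nrow(scores))
  s_y <- ifelse(label == 1L, scores[, 2L], scores[, 1L])
  s_other <- 1 - s_y
  0.5 - (s_y - s_other) / 2
}

#' Mondrian conformal p-value
#'
#' Rank-based p-value of a test nonconformity score against the calibration
#' scores of the hypothesised class:
#' \deqn{p = (\#\{i : nc_i \ge nc_{test}\} + 1) / (n + 1).}
#' Ties count towards the numerator (non-smoothed, conservative). With
#' \code{smoothed = TRUE} ties are broken by an independent uniform draw,
#' giving exactly uniform p-values under exchangeability.
#'
#' With \eqn{n} same-class calibration examples only the \eqn{n + 1} values
#' \eqn{1/(n+1), \dots, 1} are achievable, which bounds the calibration
#' resolution attainable for rare classes.
#'
#' @param cal_nc Numeric vector of calibration nonconformity scores (may be
#'   empty, in which case every p-value is 1).
#' @param test_nc Numeric vector of test nonconformity scores.
#' @param smoothed Randomise ties (default \code{FALSE}).
#' @param seed Seed for the tie-breaking uniforms when \code{smoothed}.
#' @return Numeric vector of p-values in \code{(0, 1]}, one per test score.
#' @export
mondrian_pvalue <- function(cal_nc, test_nc, smoothed = FALSE, seed = 1L) {
  n <- length(cal_nc)
  if (n == 0L) return(rep(1, length(test_nc)))
  ge <- vapply(test_nc, function(t) sum(cal_nc >= t), numeric(1))
  if (!smoothed) return((ge + 1) / (n + 1))
  gt <- vapply(test_nc, function(t) sum(cal_nc > t), numeric(1))
  set.seed(seed)
  u <- stats::runif(length(test_nc))
  (gt + u * (ge - gt + 1)) / (n + 1)
}

#' Prediction set at a significance level
#'
#' A label is included iff its p-value strictly exceeds the significance
#' level \code{epsilon}; the possible sets are the empty set, \{0\}, \{1\}
#' and \{0,1\}.
#'
#' @param p0,p1 Class-conditional p-values (equal-length vectors).
#' @param epsilon Significance level in \code{[0, 1]}.
#' @return A data frame with logical columns \code{in0}, \code{in1} and a
#'   factor column \code{set} in \code{c("empty", "0", "1", "both")}.
#' @export
prediction_set <- function(p0, p1, epsilon) {
  stopifnot(length(p0) == length(p1), epsilon >= 0, epsilon <= 1)
  in0 <- p0 > epsilon
  in1 <- p1 > epsilon
  set <- ifelse(in0 & in1, "both", ifelse(in0, "0", ifelse(in1, "1", "empty")))
  data.frame(in0 = in0, in1 = in1,
             set = factor(set, levels = c("empty", "0", "1", "both")))
}

#' Fit an inductive Mondrian conformal predictor
#'
#' The score model is fitted on the proper training set only; each
#' calibration example is scored and its margin nonconformity under its
#' true label is stored, grouped by class (the Mondrian condition), so that
#' p-values are class-conditional.
#'
#' @param x_prop,y_prop Proper training features and 0/1 labels.
#' @param x_cal,y_cal Calibration features and labels; both classes must be
#'   present.
#' @param spec A \code{\link{score_model_spec}}.
#' @param seed Seed passed to the score model fit.
#' @return An object of class \code{icp} with elements \code{model},
#'   \code{cal_nc} (list \code{"0"}, \code{"1"} of sorted scores) and
#'   \code{sizes}.
#' @export
fit_icp <- function(x_prop, y_prop, x_cal, y_cal, spec = score_model_spec(), seed = 1L) {
  y_cal <- as.integer(y_cal)
  if (length(unique(y_cal)) < 2L)
    stop("both classes must be present in the calibration set")
  model <- fit_score_model(spec, x_prop, y_prop, seed = seed)
  sc <- predict_scores(model, x_cal)
  nc <- margin_nc(sc, y_cal)
  cal_nc <- list(`0` = sort(nc[y_cal == 0L]), `1` = sort(nc[y_cal == 1L]))
  structure(list(model = model,
                 cal_nc = cal_nc,
                 sizes = c(n0 = length(cal_nc[["0"]]), n1 = length(cal_nc[["1"]]))),
            class = "icp")
}

#' Class-conditional p-values from an ICP
#'
#' Each test example is scored, its nonconformity computed under each
#' hypothesised label, and ranked against the calibration scores of the
#' matching class.
#'
#' @param icp A fitted \code{\link{fit_icp}} object.
#' @param x Test feature matrix.
#' @return A data frame with columns \code{p0} and \code{p1}.
#' @export
predict_icp <- function(icp, x) {
  stopifnot(inherits(icp, "icp"))
  sc <- predict_scores(icp$model, x)
  nc0 <- margin_nc(sc, 0L)
  nc1 <- margin_nc(sc, 1L)
  data.frame(p0 = mondrian_pvalue(icp$cal_nc[["0"]], nc0),
             p1 = mondrian_pvalue(icp$cal_nc[["1"]], nc1))
}

#' Replace an ICP's calibration set without refitting its score model
#'
#' The recalibration update strategy: the fitted score model is retained
#' and only the stored calibration nonconformity scores are recomputed on
#' new data. This restores validity when the new calibration data are
#' exchangeable with the prediction target, at no training cost.
#'
#' @param icp A fitted \code{icp}.
#' @param x_cal,y_cal New calibration data; both classes must be present.
#' @return An \code{icp} sharing the untouched score model.
#' @export
recalibrate_icp <- function(icp, x_cal, y_cal) {
  stopifnot(inherits(icp, "icp"))
  y_cal <- as.integer(y_cal)
  if (length(unique(y_cal)) < 2L)
    stop("both classes must be present in the new calibration set")
  sc <- predict_scores(icp$model, x_cal)
  nc <- margin_nc(sc, y_cal)
  icp$cal_nc <- list(`0` = sort(nc[y_cal == 0L]), `1` = sort(nc[y_cal == 1L]))
  icp$sizes <- c(n0 = length(icp$cal_nc[["0"]]), n1 = length(icp$cal_nc[["1"]]))
  icp
}
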