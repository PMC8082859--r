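#' Specify the underlying score model of a conformal predictor
#'
#' The conformal layer only requires a model that emits per-class scores in
#' \code{[0, 1]} summing to one for each example; everything downstream
#' (nonconformity, p-values, prediction sets) is agnostic to how those scores
#' are produced. Two algorithms are provided: a support-vector classifier with
#' RBF kernel and Platt-scaled class probabilities (the production default,
#' \code{C = 50}, \code{gamma = 0.002}), and a nearest-centroid model whose
#' scores are a softmax over negative squared distances to the class
#' centroids. The centroid model is deterministic and fast, which makes it the
#' workhorse for property-style testing; the conformal guarantees hold for
#' either.
#'
#' @param algorithm "svm" or "centroid".
#' @param C Cost parameter of the SVM (> 0).
#' @param gamma RBF kernel width (> 0).
#' @return An object of class \code{score_model_spec}.
#' @export
score_model_spec <- function(algorithm = c("svm", "centroid"), C = 50, gamma = 0.002) {
  algorithm <- match.arg(algorithm)
  stopifnot(C > 0, gamma > 0)
  structure(list(algorithm = algorithm, C = C, gamma = gamma),
            class = "score_model_spec")
}

#' Fit an underlying score model
#'
#' @param spec A \code{\link{score_model_spec}}.
#' @param x Numeric feature matrix (dense or \code{Matrix} sparse).
#' @param y Binary labels (0/1), both classes present.
#' @param seed Integer seed controlling any internal randomness (the SVM's
#'   Platt calibration uses internal cross-validation).
#' @return A fitted model of class \code{cp_score_model}.
#' @export
fit_score_model <- function(spec, x, y, seed = 1L) {
  stopifnot(inherits(spec, "score_model_spec"))
  x <- as.matrix(x)
  y <- as.integer(y)
  if (nrow(x) != length(y)) stop("x and y must have matching lengths")
  if (length(unique(y)) < 2L) stop("both classes must be present in the proper training set")
  fit <- switch(spec$algorithm,
    svm = {
      set.seed(seed)
      e1071::svm(x, factor(y, levels = c(0L, 1L)), kernel = "radial",
                 cost = spec$C, gamma = spec$gamma, probability = TRUE,
                 scale = FALSE)
    },
    centroid = {
      list(mu0 = colMeans(x[y == 0L, , drop = FALSE]),
           mu1 = colMeans(x[y == 1L, , drop = FALSE]))
    })
  structure(list(spec = spec, fit = fit, d = ncol(x)),
            class = "cp_score_model")
}

#' Per-class scores of a fitted score model
#'
#' @param model A \code{cp_score_model}.
#' @param x Feature matrix with the training dimensionality.
#' @return An \code{n x 2} matrix with columns \code{"0"} and \code{"1"};
#'   rows are nonnegative and sum to 1.
#' @export
predict_scores <- function(model, x) {
  stopifnot(inherits(model, "cp_score_model"))
  x <- as.matrix(x)
  if (ncol(x) != model$d)
    stop(sprintf("feature dimension mismatch: model expects %d, got %d", model$d, ncol(x)))
  s <- switch(model$spec$algorithm,
    svm = {
      pr <- attr(stats::predict(model$fit, x, probability = TRUE), "probabilities")
      cbind(`0` = pr[, "0"], `1` = pr[, "1"])
    },
    centroid = {
      d0 <- rowSums(sweep(x, 2, model$fit$mu0)^2)
      d1 <- rowSums(sweep(x, 2, model$fit$mu1)^2)
      # softmax over negative squared distances, numerically stabilised
      m <- pmin(d0, d1)
      e0 <- exp(-(d0 - m) / 2); e1 <- exp(-(d1 - m) / 2)
      cbind(`0` = e0 / (e0 + e1), `1` = e1 / (e0 + e1))
    })
  rownames(s) <- NULL
  s
}
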