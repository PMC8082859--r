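# Stratified index helpers shared by the aggregation layer and the
# experiment orchestration. All randomness flows through an explicit seed.

# derive a stream-specific seed that stays inside R's 32-bit integer range
.seed_mix <- function(seed, ...) {
  v <- as.double(seed) %% 2147483647
  for (k in c(...)) v <- (v * 48271 + as.double(k)) %% 2147483647
  as.integer(v)
}

#' Stratified proper-training / calibration split
#'
#' @param y 0/1 label vector.
#' @param cal_fraction Fraction of each class set aside for calibration.
#' @param seed Integer seed.
#' @return List with integer index vectors \code{prop} and \code{cal};
#'   per class, the calibration count is \code{round(n_class * cal_fraction)}.
#' @export
stratified_split <- function(y, cal_fraction = 0.3, seed = 1L) {
  y <- as.integer(y)
  set.seed(seed)
  cal <- integer(0)
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    n_cal <- round(length(idx) * cal_fraction)
    cal <- c(cal, sample(idx, n_cal))
  }
  cal <- sort(cal)
  list(prop = setdiff(seq_along(y), cal), cal = cal)
}

#' Stratified fold assignment
#'
#' @param y 0/1 label vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold indices in \code{1..k}; per class, fold
#'   sizes differ by at most one.
#' @export
stratified_folds <- function(y, k = 5L, seed = 1L) {
  y <- as.integer(y)
  if (any(table(factor(y, levels = c(0L, 1L))) < k))
    stop(sprintf("each class needs at least %d examples for %d stratified folds", k, k))
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in c(0L, 1L)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Fit an aggregated conformal predictor (ACP)
#'
#' Trains \code{n_models} ICPs, each on an independent stratified
#' proper-training/calibration split of the same training set, and at
#' prediction time aggregates the per-ICP p-values by their median.
#'
#' @param x,y Training features and 0/1 labels.
#' @param n_models Number of aggregated ICPs (default 20).
#' @param cal_fraction Calibration fraction per split (default 0.3).
#' @param spec A \code{\link{score_model_spec}}.
#' @param seed Integer seed; splits and fits are reproducible from it.
#' @param splits Optional pre-computed list of \code{n_models} splits (each
#'   with \code{prop} and \code{cal} index vectors), e.g. from a persisted
#'   split plan; overrides internal splitting.
#' @return An object of class \code{acp}.
#' @export
acp_fit <- function(x, y, n_models = 20L, cal_fraction = 0.3,
                    spec = score_model_spec(), seed = 1L, splits = NULL) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (any(table(factor(y, levels = c(0L, 1L))) < 2L))
    stop("both classes need at least 2 examples")
  if (is.null(splits)) {
    splits <- lapply(seq_len(n_models), function(i)
      stratified_split(y, cal_fraction, seed = .seed_mix(seed, 1L, i)))
  } else {
    n_models <- length(splits)
  }
  icps <- lapply(seq_len(n_models), function(i) {
    sp <- splits[[i]]
    fit_icp(x[sp$prop, , drop = FALSE], y[sp$prop],
            x[sp$cal, , drop = FALSE], y[sp$cal],
            spec = spec, seed = seed + i)
  })
  structure(list(icps = icps, splits = splits, cal_fraction = cal_fraction,
                 spec = spec, seed = seed),
            class = "acp")
}

#' Median-aggregated p-values from an ACP
#'
#' Per class, the aggregated p-value is the median of the per-ICP p-values
#' (even count: mean of the two middle values).
#'
#' @param acp A fitted \code{\link{acp_fit}} object.
#' @param x Test feature matrix.
#' @return Data frame with columns \code{p0}, \code{p1}.
#' @export
acp_predict <- function(acp, x) {
  stopifnot(inherits(acp, "acp"))
  pv <- lapply(acp$icps, predict_icp, x = x)
  m0 <- do.call(cbind, lapply(pv, `[[`, "p0"))
  m1 <- do.call(cbind, lapply(pv, `[[`, "p1"))
  data.frame(p0 = apply(m0, 1, stats::median),
             p1 = apply(m1, 1, stats::median))
}

#' Recalibrate every ICP of an ACP on a new calibration set
#'
#' All fitted score models are kept; each ICP's calibration nonconformity
#' scores are recomputed on the (entire) new calibration set.
#'
#' @param acp A fitted \code{acp}.
#' @param x_cal,y_cal New calibration data.
#' @return The recalibrated \code{acp}.
#' @export
acp_recalibrate <- function(acp, x_cal, y_cal) {
  stopifnot(inherits(acp, "acp"))
  acp$icps <- lapply(acp$icps, recalibrate_icp, x_cal = x_cal, y_cal = y_cal)
  acp
}

#' Fit a synergy conformal predictor (SCP)
#'
#' One fixed stratified calibration set is drawn; the remaining proper
#' training set is divided into \code{k} equally sized stratified partitions,
#' one score model per partition. Each calibration example's stored
#' nonconformity is the mean of its margin nonconformity over the \code{k}
#' sub-models, and test nonconformities are averaged the same way before the
#' p-value ranking — averaging happens before, not after, the conformal
#' step, which preserves the validity guarantee.
#'
#' @param x,y Training features and 0/1 labels.
#' @param k Number of proper-training partitions (default 4).
#' @param cal_fraction Fixed calibration fraction (default 0.3).
#' @param spec A \code{\link{score_model_spec}}.
#' @param seed Integer seed.
#' @return An object of class \code{scp}.
#' @export
scp_fit <- function(x, y, k = 4L, cal_fraction = 0.3,
                    spec = score_model_spec(), seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  sp <- stratified_split(y, cal_fraction, seed = .seed_mix(seed, 2L, 0L))
  y_cal <- y[sp$cal]
  if (length(unique(y_cal)) < 2L)
    stop("both classes must be present in the fixed calibration set")
  # stratified equal partitions: deal each class round-robin, continuing the
  # cycle across classes so total partition sizes differ by at most one
  part <- integer(length(sp$prop))
  set.seed(.seed_mix(seed, 2L, 1L))
  offset <- 0L
  for (cls in c(0L, 1L)) {
    idx <- sample(which(y[sp$prop] == cls))
    part[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
    offset <- offset + length(idx)
  }
  models <- lapply(seq_len(k), function(j) {
    pj <- sp$prop[part == j]
    if (length(unique(y[pj])) < 2L)
      stop(sprintf("partition %d is missing a class", j))
    fit_score_model(spec, x[pj, , drop = FALSE], y[pj], seed = seed + j)
  })
  x_cal <- x[sp$cal, , drop = FALSE]
  nc_cal <- rowMeans(vapply(models, function(m)
    margin_nc(predict_scores(m, x_cal), y_cal), numeric(length(y_cal))))
  structure(list(sub_models = models,
                 cal_nc_avg = list(`0` = sort(nc_cal[y_cal == 0L]),
                                   `1` = sort(nc_cal[y_cal == 1L])),
                 split = sp, partitions = part, k = k, spec = spec, seed = seed),
            class = "scp")
}

#' P-values from an SCP
#'
#' @param scp A fitted \code{\link{scp_fit}} object.
#' @param x Test feature matrix.
#' @return Data frame with columns \code{p0}, \code{p1}.
#' @export
scp_predict <- function(scp, x) {
  stopifnot(inherits(scp, "scp"))
  x <- as.matrix(x)
  n <- nrow(x)
  scores <- lapply(scp$sub_models, predict_scores, x = x)
  nc0 <- rowMeans(vapply(scores, function(s) margin_nc(s, 0L), numeric(n)))
  nc1 <- rowMeans(vapply(scores, function(s) margin_nc(s, 1L), numeric(n)))
  data.frame(p0 = mondrian_pvalue(scp$cal_nc_avg[["0"]], nc0),
             p1 = mondrian_pvalue(scp$cal_nc_avg[["1"]], nc1))
}
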