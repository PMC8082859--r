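test_that("margin nonconformity follows the margin formula and its bounds", {
  s <- rbind(c(0.9, 0.1), c(0.5, 0.5), c(1.0, 0.0))
  expect_equal(margin_nc(s, c(1L, 1L, 0L)), c(0.9, 0.5, 0.0))
  expect_equal(margin_nc(s, c(0L, 0L, 1L)), c(0.1, 0.5, 1.0))
  # random scores stay in [0, 1]
  set.seed(42)
  p <- runif(200)
  sc <- cbind(p, 1 - p)
  expect_true(all(margin_nc(sc, rbinom(200, 1, 0.5)) >= 0))
  expect_true(all(margin_nc(sc, rbinom(200, 1, 0.5)) <= 1))
  expect_error(margin_nc(rbind(c(0.6, 0.6)), 1L), "sum to 1")
})

test_that("mondrian p-values match a brute-force recount", {
  expect_equal(mondrian_pvalue(c(0.1, 0.2, 0.3, 0.4), 0.25), 0.6)
  expect_equal(mondrian_pvalue(numeric(0), 0.7), 1.0)
  set.seed(7)
  for (i in 1:50) {
    cal <- round(runif(sample(0:30, 1)), 2)  # rounding forces ties
    tst <- round(runif(5), 2)
    expect_equal(mondrian_pvalue(cal, tst),
                 vapply(tst, function(t) oracle_pvalue(cal, t), numeric(1)))
  }
})

test_that("eight same-class calibration examples admit exactly nine p-values", {
  cal <- sort(runif(8))
  probe <- sort(unique(c(cal, cal - 1e-9, cal + 1e-9, 0, 1)))
  pv <- unique(mondrian_pvalue(cal, probe))
  expect_length(pv, 9L)
  expect_setequal(round(pv, 10), round((1:9) / 9, 10))
})

test_that("smoothed p-values preserve order and randomise ties", {
  cal <- c(0.2, 0.2, 0.5)
  p1 <- mondrian_pvalue(cal, 0.2, smoothed = TRUE, seed = 1)
  p2 <- mondrian_pvalue(cal, 0.2, smoothed = TRUE, seed = 2)
  expect_false(isTRUE(all.equal(p1, p2)))
  expect_true(p1 <= mondrian_pvalue(cal, 0.2))  # never above the conservative value
})

test_that("prediction sets use the strict p > epsilon rule", {
  ps <- prediction_set(0.6, 0.15, 0.2)
  expect_equal(as.character(ps$set), "0")
  expect_equal(as.character(prediction_set(0.3, 0.9, 1.0)$set), "empty")
  expect_equal(as.character(prediction_set(0.1, 0.05, 0)$set), "both")
  # boundary: p exactly equal to epsilon is excluded
  expect_equal(as.character(prediction_set(0.2, 0.5, 0.2)$set), "1")
})

test_that("prediction sets are nested across significance levels", {
  b <- small_batches(seed = 3)
  icp <- small_icp(b)
  pv <- predict_icp(icp, b$test$x[1:200, ])
  eps <- sort(runif(6))
  for (i in seq_len(length(eps) - 1)) {
    lo <- prediction_set(pv$p0, pv$p1, eps[i])
    hi <- prediction_set(pv$p0, pv$p1, eps[i + 1])
    expect_true(all(!hi$in0 | lo$in0))
    expect_true(all(!hi$in1 | lo$in1))
  }
})

test_that("fit_icp books calibration scores per class and is deterministic", {
  b <- small_batches(seed = 5)
  icp <- small_icp(b, seed = 9)
  expect_s3_class(icp, "icp")
  sp <- stratified_split(b$train$y, 0.3, seed = 9)
  expect_equal(unname(icp$sizes["n1"]), sum(b$train$y[sp$cal] == 1))
  expect_equal(unname(icp$sizes["n0"]), sum(b$train$y[sp$cal] == 0))
  expect_true(all(unlist(icp$cal_nc) >= 0) && all(unlist(icp$cal_nc) <= 1))
  expect_false(is.unsorted(icp$cal_nc[["0"]]))
  icp2 <- small_icp(b, seed = 9)
  expect_identical(icp$cal_nc, icp2$cal_nc)
})

test_that("fit_icp rejects calibration sets missing a class", {
  b <- small_batches(seed = 2)
  keep <- b$train$y == 0
  expect_error(
    fit_icp(b$train$x[1:100, ], b$train$y[1:100],
            b$train$x[keep, ][1:20, ], b$train$y[keep][1:20],
            spec = centroid_spec()),
    "both classes")
})

test_that("well-separated training data yields confident calibration scores", {
  set.seed(11)
  n <- 100
  x <- rbind(matrix(rnorm(n * 2, -10), n, 2), matrix(rnorm(n * 2, 10), n, 2))
  y <- rep(c(0L, 1L), each = n)
  pick <- c(1:30, n + (1:30))
  icp <- fit_icp(x[-pick, ], y[-pick], x[pick, ], y[pick], spec = centroid_spec())
  expect_true(all(unlist(icp$cal_nc) < 0.5))
})

test_that("a calibration point re-presented as a test point is conforming", {
  b <- small_batches(seed = 13)
  sp <- stratified_split(b$train$y, 0.3, seed = 13)
  icp <- fit_icp(b$train$x[sp$prop, ], b$train$y[sp$prop],
                 b$train$x[sp$cal, ], b$train$y[sp$cal], spec = centroid_spec())
  i <- sp$cal[1]
  y_i <- b$train$y[i]
  pv <- predict_icp(icp, b$train$x[i, , drop = FALSE])
  p_true <- if (y_i == 1) pv$p1 else pv$p0
  n_y <- unname(icp$sizes[paste0("n", y_i)])
  expect_gte(p_true, 1 / (n_y + 1))
  # oracle recount: its own nc is in the calibration list, so rank >= 1
  sc <- predict_scores(icp$model, b$train$x[i, , drop = FALSE])
  nc <- margin_nc(sc, y_i)
  expect_equal(p_true, oracle_pvalue(icp$cal_nc[[as.character(y_i)]], nc))
})

test_that("true-class p-values are super-uniform under exchangeability", {
  b <- generate_batches(drift_scenario(n_train = 1500, n_test = 2000,
                                       n_score = 10, d = 10,
                                       active_fraction = 0.3, seed = 17))
  icp <- small_icp(b, seed = 17)
  pv <- predict_icp(icp, b$test$x)
  # Mondrian guarantee is class-conditional; the empirical exceedance rate
  # fluctuates with both the test draw and the shared calibration quantiles,
  # so the Monte-Carlo tolerance combines both variance contributions.
  for (cls in c(0L, 1L)) {
    sel <- b$test$y == cls
    p_true <- if (cls == 1L) pv$p1[sel] else pv$p0[sel]
    n <- length(p_true)
    n_cal <- unname(icp$sizes[paste0("n", cls)])
    for (t in seq(0.05, 0.95, by = 0.05)) {
      se <- sqrt(t * (1 - t) * (1 / n + 1 / n_cal))
      expect_lte(mean(p_true <= t), t + 3 * se)
    }
  }
})

test_that("predict_icp validates the feature dimension", {
  b <- small_batches(seed = 19)
  icp <- small_icp(b)
  expect_error(predict_icp(icp, b$test$x[, 1:3]), "dimension")
  pv <- predict_icp(icp, b$test$x[1, , drop = FALSE])
  expect_equal(nrow(pv), 1L)
})

test_that("recalibration swaps scores but never touches the fitted model", {
  b <- small_batches(seed = 23)
  icp <- small_icp(b)
  re <- recalibrate_icp(icp, b$score$x, b$score$y)
  expect_identical(re$model, icp$model)
  expect_equal(sum(re$sizes), length(b$score$y))
  expect_error(recalibrate_icp(icp, b$score$x[b$score$y == 0, ],
                               b$score$y[b$score$y == 0]), "both classes")
})

test_that("conformal properties hold with the SVM score model too", {
  b <- small_batches(n = 300, seed = 29)
  sp <- stratified_split(b$train$y, 0.3, seed = 1)
  icp <- fit_icp(b$train$x[sp$prop, ], b$train$y[sp$prop],
                 b$train$x[sp$cal, ], b$train$y[sp$cal],
                 spec = score_model_spec("svm"), seed = 4)
  pv <- predict_icp(icp, b$test$x)
  sets <- prediction_set(pv$p0, pv$p1, 0.2)
  err <- error_rate(sets, b$test$y)
  expect_lte(err, 0.2 + 3 * sqrt(0.2 * 0.8 / nrow(b$test$x)))
  icp2 <- fit_icp(b$train$x[sp$prop, ], b$train$y[sp$prop],
                  b$train$x[sp$cal, ], b$train$y[sp$cal],
                  spec = score_model_spec("svm"), seed = 4)
  expect_identical(icp$cal_nc, icp2$cal_nc)
})
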