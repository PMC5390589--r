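# small deterministic Gaussian feature sets for classifier tests
gaussSet <- function(n0, n1, d = 20, shift = 2, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n0 * d), n0, d), matrix(rnorm(n1 * d), n1, d))
  X[seq_len(n0), seq_len(5)] <- X[seq_len(n0), seq_len(5)] + shift
  list(X = X, y = c(rep(0L, n0), rep(1L, n1)))
}

test_that("weighted linear SVM separates separable data and validates", {
  x <- matrix(c(seq(-5, -1, length.out = 10),
                seq(1, 5, length.out = 10)), ncol = 1)
  y <- rep(c(0L, 1L), each = 10)
  fit <- fitWeightedLinearSvm(x, y)
  expect_equal(predict(fit, x), y)
  # symmetric data, equal weights: boundary near the midpoint
  expect_equal(predict(fit, matrix(c(-0.5, 0.5), ncol = 1)), c(0L, 1L))
  expect_error(fitWeightedLinearSvm(x, rep(1L, 20)), "both classes")
  expect_error(fitWeightedLinearSvm(x, y, weights = c("0" = 0, "1" = 1)),
               "> 0")
  expect_error(predict(fit, matrix(1, 1, 3)), "dimension")
  # batch prediction equals concatenated single predictions
  singles <- vapply(seq_len(nrow(x)), function(i)
    predict(fit, x[i, , drop = FALSE]), integer(1))
  expect_equal(predict(fit, x), singles)
})

test_that("raising the minority weight raises minority recall", {
  gs <- gaussSet(15, 85, shift = 1.2, seed = 3)   # overlapping, 15% minority
  rec <- vapply(c(1, 8), function(w) {
    fit <- fitWeightedLinearSvm(gs$X, gs$y, weights = c("0" = w, "1" = 1))
    pred <- predict(fit, gs$X)
    mean(pred[gs$y == 0L] == 0L)
  }, numeric(1))
  expect_gte(rec[2], rec[1])
})

test_that("confusion counts and metrics follow the printed formulas", {
  cc <- confusionCounts(rep(1, 5), rep(1, 5))
  expect_equal(cc[c("TP", "TN", "FP", "FN")],
               list(TP = 5L, TN = 0L, FP = 0L, FN = 0L))
  cc2 <- confusionCounts(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(cc2[c("TP", "FN", "FP", "TN")],
               list(TP = 1L, FN = 1L, FP = 1L, TN = 1L))
  expect_error(confusionCounts(1:3, 1:2), "length")
  m <- computeMetrics(list(TP = 9, FN = 1, TN = 3, FP = 1))
  expect_equal(m$sen, 0.9)
  expect_equal(m$spe, 0.75)
  expect_equal(m$acc, 12 / 14)
  expect_equal(m$ppv, 0.9)
  expect_equal(m$npv, 0.75)
  expect_equal(m$f1, 18 / 20)
  # metric identities
  expect_equal(m$f1, 2 * m$ppv * m$sen / (m$ppv + m$sen))
  P <- 10; N <- 4
  expect_equal(m$acc, (m$sen * P + m$spe * N) / (P + N))
  # undefined metrics are NA, never 0
  m2 <- computeMetrics(list(TP = 4, FN = 0, TN = 0, FP = 0))
  expect_equal(m2$sen, 1); expect_equal(m2$acc, 1)
  expect_true(is.na(m2$spe) && is.na(m2$npv))
  m3 <- computeMetrics(list(TP = 0, FN = 0, TN = 0, FP = 0))
  expect_true(all(is.na(unlist(m3[c("acc", "sen", "spe")]))))
  m4 <- computeMetrics(list(TP = 2, FN = 2, TN = 2, FP = 2))
  expect_equal(m4$acc, 0.5)
})

test_that("balance metric matches the class-weight table recomputations", {
  expect_equal(round(100 * balanceMetric(0.9426, 0.7540), 2), 71.07)
  expect_equal(round(100 * balanceMetric(0.9379, 0.7293), 2), 68.40)
  expect_equal(balanceMetric(1, 0), 0)
  expect_equal(balanceMetric(1, 0, "sqrt"), 0)
  expect_error(balanceMetric(1.2, 0.5), "0, 1")
  # product mode is never above sqrt mode; equality iff equal or zero
  set.seed(77)
  for (i in 1:20) {
    s <- runif(2)
    expect_lte(balanceMetric(s[1], s[2]),
               balanceMetric(s[1], s[2], "sqrt") + 1e-12)
  }
  expect_equal(balanceMetric(0.6, 0.6), balanceMetric(0.6, 0.6, "sqrt")^2)
})

test_that("cross-validation stratifies, averages and reproduces", {
  gs <- gaussSet(30, 70, shift = 3, seed = 5)
  cfg <- cvConfig(k = 5, repeats = 2, seed = 9)
  cv <- crossValidate(gs$X, gs$y, cfg)
  expect_equal(nrow(cv$folds), 10L)
  # separable: perfect averaged accuracy
  expect_equal(cv$average$acc, 1)
  # determinism
  cv2 <- crossValidate(gs$X, gs$y, cfg)
  expect_identical(cv$average, cv2$average)
  # stratification: every fold's class ratio within one sample of global
  fold <- PCAHashNet:::makeFolds(gs$y, 5, TRUE, seed = 4)
  for (f in 1:5) {
    expect_equal(sum(fold == f), 20)
    expect_lte(abs(sum(gs$y[fold == f] == 0) - 6), 1)
  }
  expect_error(crossValidate(gs$X[c(1:3, 31:40), ], gs$y[c(1:3, 31:40)],
                             cvConfig(k = 5)), "fewer members")
})

test_that("fold sizes follow the protocol arithmetic", {
  y <- c(rep(0L, 48), rep(1L, 267))
  fold <- PCAHashNet:::makeFolds(y, 5, TRUE, seed = 1)
  expect_true(all(table(fold) == 63))
})

test_that("weight sweep tabulates one row per weight and flags the best", {
  gs <- gaussSet(15, 85, shift = 1.2, seed = 3)
  cfg <- cvConfig(k = 5, repeats = 1, seed = 9)
  sw <- weightSweep(gs$X, gs$y, weights = 1:9, config = cfg)
  expect_equal(nrow(sw), 9L)
  expect_equal(sum(sw$best), 1L)
  expect_equal(sw$weight[sw$best], sw$weight[which.max(sw$g)])
  # minority correctness at weight 9 is at least that at weight 1
  expect_gte(sw$spe[sw$weight == 9], sw$spe[sw$weight == 1])
  # a single weight reproduces the plain cross-validation row
  sw1 <- weightSweep(gs$X, gs$y, weights = 1, config = cfg)
  cv1 <- crossValidate(gs$X, gs$y, cfg)
  expect_equal(sw1$acc, cv1$average$acc)
  expect_equal(sw1$g, cv1$average$g)
})

test_that("grid search is exhaustive with a first-in-grid tie rule", {
  gs <- gaussSet(10, 20, shift = 3, seed = 11)
  # features independent of the hyperparameters: constant objective
  fn <- function(p) gs$X
  res <- gridSearchHyperParams(fn, gs$y,
                               grids = list(gamma = c(0, 2, 4), a = c(0, 1)),
                               seed = 2)
  expect_equal(res$params@gamma, 0)      # tie -> first point in grid order
  expect_equal(res$params@a, 0L)
  expect_equal(nrow(res$scores), 6L)
  # single-point grid returns that point
  res1 <- gridSearchHyperParams(fn, gs$y, grids = list(eps = 1e-5), seed = 2)
  expect_equal(res1$params@eps, 1e-5)
  # a gamma value that provably separates is selected: features are
  # informative only at gamma = 4
  fn2 <- function(p) if (p@gamma == 4) gs$X else matrix(0, nrow(gs$X), 20)
  res2 <- gridSearchHyperParams(fn2, gs$y,
                                grids = list(gamma = c(0, 2, 4)), seed = 2)
  expect_equal(res2$params@gamma, 4)
  expect_error(gridSearchHyperParams(fn, gs$y, grids = list(), seed = 2),
               "empty")
  expect_error(gridSearchHyperParams(fn, gs$y,
                                     grids = list(foo = 1), seed = 2),
               "unknown")
})

test_that("default grids follow the printed search ranges", {
  g <- defaultHyperGrids()
  expect_equal(g$eps, 10^seq(-10, 0))
  expect_equal(g$a, c(0, 1))
  expect_equal(g$gamma, seq(0, 10, 2))
  expect_equal(g$alpha, 10^seq(-6, 2))
  expect_equal(g$beta, seq(0, 1, 0.25))
  # sigma grid honours the stated generating formula (two points)
  expect_equal(g$sigma, 315 * c(0.59, 0.60) / 84)
})

test_that("explicit weights agree with the solver's own predictions and
           round-trip through flat text", {
  gs <- gaussSet(20, 30, shift = 1, seed = 13)   # overlapping classes
  fit <- fitWeightedLinearSvm(gs$X, gs$y, weights = c("0" = 3, "1" = 1))
  # dual route: our w/b decision vs e1071's label predictions
  ours <- predict(fit, gs$X)
  theirs <- as.integer(as.character(stats::predict(fit$svm, gs$X)))
  expect_equal(ours, theirs)
  f <- withr::local_tempfile(fileext = ".txt")
  writeSvmModel(fit, f)
  back <- readSvmModel(f)
  expect_equal(back$w, fit$w, tolerance = 1e-12)
  expect_equal(back$b, fit$b, tolerance = 1e-12)
  expect_equal(predict(back, gs$X), ours)
})
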