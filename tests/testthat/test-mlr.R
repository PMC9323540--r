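test_that("OLS matches the normal-equation oracle and its identities", {
  X <- randomStdMatrix(12, 3, seed = 21)
  y <- drop(X %*% c(1.5, -0.5, 0.2)) + rnorm(12, sd = 0.3)
  m <- fitOls(X, y)
  expect_equal(unname(coef(m)), unname(olsOracle(X, y)), tolerance = 1e-8)
  # standardized columns make the intercept the response mean
  expect_equal(m@beta0, mean(y), tolerance = 1e-9)

  # noise-free linear data is reproduced exactly
  yLin <- drop(2 + X %*% c(1, 2, 3))
  mLin <- fitOls(X, yLin)
  expect_equal(predict(mLin, X), yLin, tolerance = 1e-10)
  expect_equal(r2Score(yLin, predict(mLin, X)), 1, tolerance = 1e-12)

  # rank deficiency is detected and reported
  Xdep <- cbind(X, dup = X[, 1])
  expect_error(fitOls(Xdep, y), "rank-deficient")
})

test_that("standardized coefficients equal unstandardized times column sd", {
  set.seed(31)
  raw <- matrix(rnorm(60, 10, 4), 20, 3,
                dimnames = list(NULL, c("a", "b", "c")))
  y <- drop(raw %*% c(0.5, -1, 2)) + rnorm(20)
  std <- scale(raw)
  mStd <- fitOls(std, y)
  mRaw <- fitOls(raw, y)
  expect_equal(mStd@betas, unname(mRaw@betas * apply(raw, 2, sd)),
               tolerance = 1e-8)
})

test_that("OMP picks by residual correlation and refits at each step", {
  X <- randomStdMatrix(20, 8, seed = 5)
  # y exactly equal to one column: that column is selected first
  y3 <- X[, 3] + 0  # noise-free
  expect_warning(m3 <- ompSelect(X, y3, 3), "residual numerically zero")
  expect_identical(descriptorNames(m3)[1], colnames(X)[3])

  # planted 2-sparse noise-free signal: OMP finds the exhaustive optimum
  y <- drop(X %*% c(0, 1.2, 0, 0, -0.8, 0, 0, 0))
  m <- ompSelect(X, y, 2)
  expect_setequal(descriptorNames(m), exhaustiveBestSubset(X, y, 2)$names)

  # k = 0: intercept-only model
  m0 <- ompSelect(X, y, 0)
  expect_length(descriptorNames(m0), 0)
  expect_equal(m0@beta0, mean(y))

  # k = p reproduces the full OLS fit
  set.seed(6)
  yFull <- drop(X %*% rnorm(8)) + rnorm(20, sd = 0.5)
  mAll <- ompSelect(X, yFull, 8)
  mOls <- fitOls(X, yFull)
  expect_equal(coef(mAll)[names(coef(mOls))], coef(mOls),
               tolerance = 1e-8)
})

test_that("training r-squared is non-decreasing along the OMP path", {
  X <- randomStdMatrix(30, 10, seed = 8)
  set.seed(9)
  y <- drop(X %*% rnorm(10)) + rnorm(30)
  r2s <- vapply(1:6, function(k)
    r2Score(y, predict(ompSelect(X, y, k), X)), numeric(1))
  expect_true(all(diff(r2s) > -1e-12))
})

test_that("the expulsion loop escapes a high-correlation proxy descriptor", {
  set.seed(77)
  n <- 40
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- x1 + x2
  # proxy correlated 0.9 with y, masking the exact two-column model
  w <- rnorm(n)
  yS <- (y - mean(y)) / sd(y)
  wR <- residuals(lm(w ~ y)); wS <- wR / sd(wR)
  proxy <- 0.9 * yS + sqrt(1 - 0.81) * wS
  X <- scale(cbind(proxy = proxy, x1 = x1, x2 = x2,
                   matrix(rnorm(n * 5), n,
                          dimnames = list(NULL, paste0("n", 1:5)))))
  folds <- assignFolds(y, 5)
  # round 0 is the masked pick
  expect_identical(descriptorNames(ompSelect(X, y, 2))[1], "proxy")
  res <- expulsionSearch(X, y, 2, folds, corrThreshold = 0.4)
  expect_setequal(descriptorNames(res$model),
                  exhaustiveBestSubset(X, y, 2)$names)
  expect_setequal(descriptorNames(res$model), c("x1", "x2"))
  # a later round beat round 0
  scores <- vapply(res$trace@rounds, function(r) r$cvR2, numeric(1))
  expect_gt(max(scores[-1]), scores[1])
})

test_that("expulsion stops immediately when no descriptor correlates strongly", {
  set.seed(15)
  n <- 80
  X <- scale(matrix(rnorm(n * 6), n, dimnames = list(NULL, letters[1:6])))
  y <- rnorm(n)  # independent of X: correlations stay small
  stopifnot(max(abs(cor(X, y))) < 0.4)
  res <- expulsionSearch(X, y, 2, assignFolds(y, 5))
  expect_length(res$trace@rounds, 1L)
  expect_true(is.na(res$trace@rounds[[1]]$expelled))
  expect_identical(res$trace@stopReason, "correlation below threshold")
})

test_that("the 20 percent rule accepts exactly at its boundary", {
  mkBuilder <- function(errs) function(k)
    list(model = sprintf("m%d", k), cvError = errs[k])

  # (0.10 - 0.08)/0.10 = 0.20: boundary case is accepted
  ch <- chooseModelSize(mkBuilder(c(0.10, 0.08, 0.075)), kMax = 3)
  expect_identical(ch$k, 2L)

  # error increases from k=1 to k=2: stay at one descriptor
  expect_identical(chooseModelSize(mkBuilder(c(0.2, 0.25)), 2)$k, 1L)

  # 0.30 -> 0.21 is a 30% correction (accept), 0.21 -> 0.18 is 14% (reject)
  ch3 <- chooseModelSize(mkBuilder(c(0.30, 0.21, 0.18)), 3)
  expect_identical(ch3$k, 2L)
  expect_identical(ch3$model, "m2")

  # a perfect one-descriptor model stops immediately
  expect_identical(chooseModelSize(mkBuilder(c(0, 0)), 2)$k, 1L)
})

test_that("model export writes a self-contained JSON document", {
  d <- makePlantedLinear(syntheticSpec(n = 30, p = 20, seed = 2))
  dm <- standardizeDescriptors(pruneDescriptors(d$X))
  m <- fitOls(as.matrix(dm)[, d$truth$signal], unname(d$y))
  f <- tempfile(fileext = ".json")
  exportModelJson(m, f, descriptorMatrix = dm,
                  provenance = list(seed = 2))
  doc <- jsonlite::read_json(f)
  expect_identical(unlist(doc$descriptors), d$truth$signal)
  expect_equal(doc$intercept, m@beta0, tolerance = 1e-12)
  expect_named(doc$standardization, c("means", "sds"))
  expect_equal(unlist(doc$coefficients), setNames(m@betas, d$truth$signal),
               tolerance = 1e-12)
})
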