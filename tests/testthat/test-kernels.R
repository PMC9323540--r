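toyLine <- function() {
  X <- matrix(seq(-1, 1, length.out = 5), 5, 1,
              dimnames = list(NULL, "x"))
  list(X = X, y = drop(2 * X[, 1] + 1))
}

test_that("gamma tokens resolve to the documented scales", {
  set.seed(4)
  X <- matrix(rnorm(40, sd = 3), 10, 4)
  expect_equal(resolveGamma("auto", X), 1 / 4)
  expect_equal(resolveGamma("scale", X), 1 / (4 * mean((X - mean(X))^2)))
  expect_equal(resolveGamma(0.25, X), 0.25)
  expect_error(resolveGamma(-1, X), "positive")
})

test_that("SVR respects the epsilon tube on degenerate and toy problems", {
  # a single training point is predicted within epsilon
  X1 <- matrix(0.5, 1, 1, dimnames = list(NULL, "a"))
  m1 <- fitSvr(X1, 2, C = 10, epsilon = 0.01)
  expect_lt(abs(predict(m1, X1) - 2), 0.01 + 1e-9)

  # five points on a line, large C, small epsilon
  toy <- toyLine()
  m <- fitSvr(toy$X, toy$y, C = 1000, epsilon = 0.01, gamma = 1)
  expect_true(all(abs(predict(m, toy$X) - toy$y) <= 2 * 0.01))
  expect_true(all(abs(m@alphas) <= m@cost * (1 + 1e-8)))
  expect_error(fitSvr(toy$X, toy$y, C = -1), "positive")
})

test_that("SVR duals match an independent generic-QP solution", {
  toy <- toyLine()
  C <- 5; eps <- 0.05; gamma <- 1
  m <- fitSvr(toy$X, toy$y, C = C, epsilon = eps, gamma = gamma)
  K <- exp(-gamma * as.matrix(dist(toy$X))^2)
  qp <- svrDualQp(K, toy$y, C, eps)
  beta <- numeric(5)
  beta[m@supportIndices] <- m@alphas
  expect_equal(beta, qp$beta, tolerance = 1e-4)
  expect_equal(m@intercept, qp$b, tolerance = 1e-4)
})

test_that("widening the tube never adds support vectors", {
  set.seed(12)
  X <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "x"))
  y <- sin(2 * X[, 1]) + rnorm(30, sd = 0.1)
  nsv <- vapply(c(0.01, 0.05, 0.1, 0.3, 0.6), function(eps)
    length(fitSvr(X, y, C = 10, epsilon = eps, gamma = 1)@supportIndices),
    integer(1))
  expect_true(all(diff(nsv) <= 0))
})

test_that("the SVR grid search scores exhaustively and keeps grid order", {
  toy <- toyLine()
  folds <- assignFolds(toy$y, 2)
  one <- HyperparamGrid(3, 0.02, list("auto"))
  t1 <- tuneSvr(toy$X, toy$y, folds, one)
  expect_equal(t1[c("C", "epsilon", "gamma")],
               list(C = 3, epsilon = 0.02, gamma = "auto"))

  # planted smooth nonlinear data where a small gamma generalizes and a
  # large gamma overfits by construction; both candidates scored explicitly
  set.seed(3)
  n <- 40
  Xs <- matrix(sort(rnorm(n)), n, 1, dimnames = list(NULL, "x"))
  ys <- sin(Xs[, 1]) + rnorm(n, sd = 0.05)
  f <- assignFolds(ys, 5)
  r2lo <- cvTestR2(svrSpec(C = 10, epsilon = 0.01, gamma = 0.1),
                   Xs, ys, f)
  r2hi <- cvTestR2(svrSpec(C = 10, epsilon = 0.01, gamma = 10),
                   Xs, ys, f)
  expect_gt(r2lo, r2hi)
  tuned <- tuneSvr(Xs, ys, f, HyperparamGrid(10, 0.01, list(0.1, 10)))
  expect_equal(tuned$gamma, 0.1)

  # the default grid is the predetermined tuning table
  g <- defaultSvrGrid()
  expect_equal(g@CValues, c(0.001, 0.005, 0.1, 0.5, 1, 5, 10, 50, 100,
                            500, 1000))
  expect_equal(g@epsilonValues, c(0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 1,
                                  5, 10))
  expect_equal(g@gammaValues, list(0.001, 0.005, 0.01, 0.05, 0.1, "auto",
                                   "scale"))
})

test_that("GPR interpolates as noise vanishes and matches explicit algebra", {
  toy <- toyLine()
  g <- fitGpr(toy$X, toy$y, sigma0 = 1, noiseLevel = 1e-8,
              lengthScale = 1, optimize = FALSE)
  expect_lt(max(abs(predict(g, toy$X) - toy$y)), 1e-6)

  # three-point problem vs the posterior mean/covariance computed with
  # hand-rolled linear algebra
  X3 <- matrix(c(-1, 0, 2), 3, 1, dimnames = list(NULL, "x"))
  y3 <- c(0.5, -0.2, 1.4)
  s0 <- 0.7; nl <- 0.05; ls <- 1.3
  g3 <- fitGpr(X3, y3, sigma0 = s0, noiseLevel = nl, lengthScale = ls,
               optimize = FALSE)
  kf <- function(A, B) s0^2 + tcrossprod(A, B) +
    exp(-as.matrix(outer(A[, 1], B[, 1], "-"))^2 / (2 * ls^2))
  Ktr <- kf(X3, X3) + diag(nl, 3)
  Xq <- matrix(c(-0.5, 1), 2, 1, dimnames = list(NULL, "x"))
  muOracle <- drop(kf(Xq, X3) %*% solve(Ktr, y3))
  covOracle <- kf(Xq, Xq) - kf(Xq, X3) %*% solve(Ktr, t(kf(Xq, X3)))
  pred <- predictGpr(g3, Xq)
  expect_equal(pred$mean, muOracle, tolerance = 1e-8)
  expect_equal(pred$cov, covOracle, tolerance = 1e-6)

  # single query point: 1x1 covariance, non-negative
  p1 <- predictGpr(g3, Xq[1, , drop = FALSE])
  expect_equal(dim(p1$cov), c(1L, 1L))
  expect_gte(p1$cov[1, 1], 0)
})

test_that("far-from-data queries revert to the prior variance", {
  # training confined to the first coordinate; the query moves far along
  # the second, so the RBF term dies and the cross-kernel is the constant
  # sigma0^2: the closed-form limit is dominated by the ||x||^2 prior term
  set.seed(8)
  Xtr <- cbind(a = rnorm(6), b = 0)
  ytr <- Xtr[, 1] + rnorm(6, sd = 0.1)
  s0 <- 0.5; nl <- 0.1; ls <- 1
  g <- fitGpr(Xtr, ytr, sigma0 = s0, noiseLevel = nl, lengthScale = ls,
              optimize = FALSE)
  R <- 50
  xq <- cbind(a = 0, b = R)
  v <- predictGpr(g, xq)$cov[1, 1]
  kf <- function(A, B) s0^2 + tcrossprod(A, B) +
    exp(-as.matrix(dist(rbind(A, B)))[seq_len(nrow(A)),
                                      nrow(A) + seq_len(nrow(B)),
                                      drop = FALSE]^2 / (2 * ls^2))
  Ktr <- kf(Xtr, Xtr) + diag(nl, 6)
  ks <- matrix(s0^2, 1, 6)  # dot product and RBF both vanish here
  vLimit <- (s0^2 + R^2 + 1) - drop(ks %*% solve(Ktr, t(ks)))
  expect_equal(v, vLimit, tolerance = 1e-4)
  expect_gt(v, 0.9 * R^2)
})

test_that("optimized marginal likelihood never falls below its start", {
  set.seed(14)
  X <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "x"))
  y <- sin(X[, 1]) + rnorm(20, sd = 0.2)
  init <- fitGpr(X, y, sigma0 = 1, noiseLevel = 0.1, lengthScale = 1,
                 optimize = FALSE)
  opt <- fitGpr(X, y, sigma0 = 1, noiseLevel = 0.1, lengthScale = 1,
                optimize = TRUE, restarts = 3, seed = 2)
  expect_gte(opt@logMarginalLikelihood, init@logMarginalLikelihood)
})

test_that("with a huge length scale and vanishing noise GPR matches OLS", {
  # the RBF term flattens to a constant and the kernel is effectively
  # constant + dot product, whose posterior mean is the least-squares fit
  set.seed(19)
  X <- matrix(rnorm(24), 12, 2, dimnames = list(NULL, c("a", "b")))
  y <- drop(1 + X %*% c(0.8, -0.4)) + rnorm(12, sd = 0.2)
  g <- fitGpr(X, y, sigma0 = 10, noiseLevel = 1e-7, lengthScale = 1e6,
              optimize = FALSE)
  ols <- fitOls(X, y)
  expect_equal(predict(g, X), unname(predict(ols, X)), tolerance = 1e-4)
})
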