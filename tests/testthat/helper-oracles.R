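# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain normal equations, exhaustive enumeration
# and explicit matrix algebra.

# best size-k subset by residual sum of squares, exhaustive over combn
exhaustiveBestSubset <- function(X, y, k) {
  best <- NULL
  bestRss <- Inf
  for (idx in asplit(utils::combn(ncol(X), k), 2L)) {
    D <- cbind(1, X[, idx, drop = FALSE])
    beta <- solve(crossprod(D), crossprod(D, y))
    rss <- sum((y - D %*% beta)^2)
    if (rss < bestRss - 1e-12) {
      bestRss <- rss
      best <- colnames(X)[idx]
    }
  }
  list(names = best, rss = bestRss)
}

# normal-equation OLS, independent of fitOls
olsOracle <- function(X, y) {
  D <- cbind(1, X)
  drop(solve(crossprod(D), crossprod(D, y)))
}

# all permutations of 1..n (n small), as a list
allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (perm in allPermutations(n - 1L))
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(perm, n, after = pos - 1L)
  out
}

# eps-SVR dual solved as a generic QP with kernlab::ipop:
# variables (alpha, alphaStar), minimize 0.5 b'Kb + eps 1'(a+a*) - y'b
# with b = a - a*, subject to sum(b) = 0 and box [0, C]
svrDualQp <- function(K, y, C, eps) {
  n <- length(y)
  H <- rbind(cbind(K, -K), cbind(-K, K))
  cvec <- c(eps - y, eps + y)
  A <- matrix(c(rep(1, n), rep(-1, n)), 1L)
  sol <- kernlab::ipop(c = cvec, H = H + diag(1e-10, 2L * n),
                       A = A, b = 0, l = rep(0, 2L * n),
                       u = rep(C, 2L * n), r = 0, sigf = 9,
                       maxiter = 200)
  x <- kernlab::primal(sol)
  beta <- x[seq_len(n)] - x[n + seq_len(n)]
  # intercept from a free support vector's KKT condition
  f0 <- drop(K %*% beta)
  tol <- C * 1e-5
  iPos <- which(x[seq_len(n)] > tol & x[seq_len(n)] < C - tol)
  iNeg <- which(x[n + seq_len(n)] > tol & x[n + seq_len(n)] < C - tol)
  bs <- c(y[iPos] - eps - f0[iPos], y[iNeg] + eps - f0[iNeg])
  list(beta = beta, b = if (length(bs)) mean(bs) else NA_real_)
}

# leave-one-out refit definition of Cook's distance
cooksDeletionOracle <- function(X, y) {
  D <- cbind(1, X)
  n <- nrow(D); p <- ncol(D)
  beta <- solve(crossprod(D), crossprod(D, y))
  yhat <- drop(D %*% beta)
  s2 <- sum((y - yhat)^2) / (n - p)
  vapply(seq_len(n), function(i) {
    bi <- solve(crossprod(D[-i, , drop = FALSE]),
                crossprod(D[-i, , drop = FALSE], y[-i]))
    sum((yhat - drop(D %*% bi))^2) / (p * s2)
  }, numeric(1))
}

# small standardized random design with named columns
randomStdMatrix <- function(n, p, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("r%02d", seq_len(n)),
                              sprintf("c%02d", seq_len(p))))
  scale(m)
}
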