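# Composite GPR kernel: k(x,x') = sigma0^2 + x.x' + exp(-||x-x'||^2/(2 l^2)),
# white noise of variance noiseLevel added on the training diagonal only.

sqDist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d, 0)
}

gprKernel <- function(A, B, sigma0, lengthScale) {
  sigma0^2 + tcrossprod(A, B) + exp(-sqDist(A, B) / (2 * lengthScale^2))
}

# Cholesky with jitter escalation 1e-10 -> 1e-6 (x10 per attempt)
cholJitter <- function(K) {
  jitter <- 1e-10
  n <- nrow(K)
  repeat {
    L <- tryCatch(chol(K + diag(jitter, n)), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = jitter))
    if (jitter >= 1e-6)
      stop(sprintf(
        "Cholesky failed up to jitter 1e-6; kernel matrix ill-conditioned (rcond ~ %.2e)",
        1 / kappa(K)))
    jitter <- jitter * 10
  }
}

gprLogLik <- function(X, y, sigma0, noiseLevel, lengthScale) {
  n <- length(y)
  K <- gprKernel(X, X, sigma0, lengthScale) + diag(noiseLevel, n)
  cj <- cholJitter(K)
  alpha <- backsolve(cj$L, forwardsolve(t(cj$L), y))
  list(lml = -0.5 * sum(y * alpha) - sum(log(diag(cj$L))) -
         n / 2 * log(2 * pi),
       L = cj$L, alpha = alpha)
}

#' Fit Gaussian process regression with a composite kernel
#'
#' Kernel: constant sigma0^2 plus dot product plus unit-amplitude squared
#' exponential of length scale l, with white noise of variance
#' \code{noiseLevel} on the training diagonal. When \code{optimize} is
#' TRUE the three hyperparameters maximize the log marginal likelihood by
#' L-BFGS-B in log space from the given initialization plus
#' \code{restarts} seeded log-uniform restarts; the best of all starts
#' (including the initialization itself, so the optimized marginal
#' likelihood never falls below its initial value) is kept.
#'
#' @param X standardized descriptor matrix.
#' @param y response vector.
#' @param sigma0,noiseLevel,lengthScale initial kernel parameters.
#' @param optimize maximize the marginal likelihood (default TRUE).
#' @param restarts number of random restarts (default 5).
#' @param seed RNG seed for the restarts (default 1).
#' @return a \linkS4class{GprModel}.
#' @export
fitGpr <- function(X, y, sigma0 = 1, noiseLevel = 0.1, lengthScale = 1,
                   optimize = TRUE, restarts = 5L, seed = 1L) {
  X <- asMatrixX(X)
  stopIfNot(nrow(X) == length(y), "X rows must match length(y)")
  stopIfNot(sigma0 > 0 && noiseLevel > 0 && lengthScale > 0,
            "initial kernel parameters must be positive")
  negll <- function(logTheta) {
    th <- exp(logTheta)
    -tryCatch(gprLogLik(X, y, th[1L], th[2L], th[3L])$lml,
              error = function(e) -Inf)
  }
  theta <- c(sigma0, noiseLevel, lengthScale)
  if (optimize) {
    lower <- log(c(1e-5, 1e-8, 1e-2))
    upper <- log(c(1e3, 1e2, 1e3))
    starts <- list(log(theta))
    if (restarts > 0L) withSeed(seed, {
      for (i in seq_len(restarts))
        starts[[i + 1L]] <- stats::runif(3L, lower, upper)
    })
    bestVal <- negll(log(theta))
    bestPar <- log(theta)
    for (s in starts) {
      opt <- tryCatch(
        stats::optim(pmin(pmax(s, lower), upper), negll,
                     method = "L-BFGS-B", lower = lower, upper = upper),
        error = function(e) NULL)
      if (!is.null(opt) && is.finite(opt$value) && opt$value < bestVal) {
        bestVal <- opt$value
        bestPar <- opt$par
      }
    }
    theta <- exp(bestPar)
  }
  ll <- gprLogLik(X, y, theta[1L], theta[2L], theta[3L])
  new("GprModel", descriptorNames = colnames(X), X = X, y = as.numeric(y),
      sigma0 = theta[1L], noiseLevel = theta[2L], lengthScale = theta[3L],
      logMarginalLikelihood = ll$lml, L = ll$L, alpha = ll$alpha)
}

#' Predictive distribution of a fitted GPR model
#'
#' Mean and covariance of the latent function at new points:
#' mean = K(X*, X) K(X, X)^{-1} y and
#' V = K(X*, X*) - K(X*, X) K(X, X)^{-1} K(X, X*), where the training
#' kernel includes the white-noise diagonal and the cross/test kernels do
#' not. The covariance is symmetrized and its diagonal clipped at 0.
#'
#' @param model a \linkS4class{GprModel}.
#' @param Xstar matrix (or \linkS4class{DescriptorMatrix}) with the
#'   model's descriptor columns.
#' @return list(mean, cov).
#' @export
predictGpr <- function(model, Xstar) {
  if (is(Xstar, "DescriptorMatrix")) Xstar <- Xstar@values
  Xstar <- asMatrixX(Xstar)
  miss <- setdiff(model@descriptorNames, colnames(Xstar))
  if (length(miss))
    stop("missing descriptor columns: ", paste(miss, collapse = ", "))
  Xs <- Xstar[, model@descriptorNames, drop = FALSE]
  Ks <- gprKernel(Xs, model@X, model@sigma0, model@lengthScale)
  mu <- drop(Ks %*% model@alpha)
  V <- forwardsolve(t(model@L), t(Ks))
  cov <- gprKernel(Xs, Xs, model@sigma0, model@lengthScale) - crossprod(V)
  cov <- (cov + t(cov)) / 2
  diag(cov) <- pmax(diag(cov), 0)
  list(mean = mu, cov = cov)
}

#' Predict (posterior mean) from a fitted GPR model
#'
#' @param object a \linkS4class{GprModel}.
#' @param newdata matrix or \linkS4class{DescriptorMatrix}.
#' @param ... ignored.
#' @return numeric vector of posterior means.
#' @export
setMethod("predict", "GprModel", function(object, newdata, ...) {
  predictGpr(object, newdata)$mean
})
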