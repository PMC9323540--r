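#' Resolve an RBF kernel scale token
#'
#' "auto" resolves to 1/p; "scale" to 1/(p * Var(X)) where Var is the
#' population variance of all matrix entries; numbers pass through.
#'
#' @param gamma positive number or token "auto"/"scale".
#' @param X training matrix the token refers to.
#' @return numeric(1).
#' @export
resolveGamma <- function(gamma, X) {
  if (is.numeric(gamma)) {
    stopIfNot(gamma > 0, "gamma must be positive")
    return(gamma)
  }
  p <- ncol(X)
  switch(match.arg(gamma, c("auto", "scale")),
         auto = 1 / p,
         scale = {
           v <- mean((X - mean(X))^2)
           stopIfNot(v > 0, "gamma 'scale' undefined on a constant matrix")
           1 / (p * v)
         })
}

#' Epsilon-insensitive support vector regression with RBF kernel
#'
#' Fits eps-SVR with kernel K(x, x') = exp(-gamma ||x - x'||^2); the dual
#' problem is solved by the libsvm SMO solver (via e1071). The returned
#' object exposes the signed dual coefficients (|alpha_i| <= C), support
#' indices and intercept.
#'
#' @param X standardized descriptor matrix.
#' @param y response vector.
#' @param C penalty (> 0).
#' @param epsilon tube half-width (> 0).
#' @param gamma kernel scale: positive number, "auto" (1/p) or "scale"
#'   (1/(p Var(X))).
#' @return an \linkS4class{SvrModel}.
#' @export
fitSvr <- function(X, y, C = 1, epsilon = 0.001, gamma = "auto") {
  X <- asMatrixX(X)
  stopIfNot(C > 0 && epsilon > 0, "C and epsilon must be positive")
  g <- resolveGamma(gamma, X)
  fit <- e1071::svm(x = X, y = y, scale = FALSE, type = "eps-regression",
                    kernel = "radial", cost = C, epsilon = epsilon,
                    gamma = g, fitted = FALSE, tolerance = 1e-6)
  empty <- is.null(fit$coefs) || fit$tot.nSV == 0L
  new("SvrModel", descriptorNames = colnames(X), cost = C,
      epsilon = epsilon, gamma = gamma, gammaValue = g,
      supportIndices = if (empty) integer(0) else as.integer(fit$index),
      alphas = if (empty) numeric(0) else as.numeric(fit$coefs),
      intercept = -fit$rho, fit = fit)
}

#' Predict from a fitted SVR model
#'
#' @param object an \linkS4class{SvrModel}.
#' @param newdata matrix or \linkS4class{DescriptorMatrix} with the
#'   model's descriptor columns.
#' @param ... ignored.
#' @return numeric vector.
#' @export
setMethod("predict", "SvrModel", function(object, newdata, ...) {
  X <- if (is(newdata, "DescriptorMatrix")) newdata@values else
    asMatrixX(newdata)
  miss <- setdiff(object@descriptorNames, colnames(X))
  if (length(miss))
    stop("missing descriptor columns: ", paste(miss, collapse = ", "))
  # with every training point inside the tube the dual is empty and the
  # model is the constant b
  if (length(object@supportIndices) == 0L)
    return(rep(object@intercept, nrow(X)))
  unname(stats::predict(object@fit,
                        X[, object@descriptorNames, drop = FALSE]))
})

#' The default SVR tuning grid
#'
#' C in \{0.001, 0.005, 0.1, 0.5, 1, 5, 10, 50, 100, 500, 1000\},
#' epsilon in \{0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 1, 5, 10\},
#' gamma in \{0.001, 0.005, 0.01, 0.05, 0.1, "auto", "scale"\}.
#'
#' @return a \linkS4class{HyperparamGrid}.
#' @export
defaultSvrGrid <- function() {
  HyperparamGrid(
    CValues = c(0.001, 0.005, 0.1, 0.5, 1, 5, 10, 50, 100, 500, 1000),
    epsilonValues = c(0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 1, 5, 10),
    gammaValues = list(0.001, 0.005, 0.01, 0.05, 0.1, "auto", "scale"))
}

#' Exhaustive SVR hyperparameter grid search
#'
#' Scores every (C, epsilon, gamma) triple of the grid by fold-averaged
#' cross-validated test r-squared under the given folds; ties go to the
#' earlier triple in grid order (C outermost, gamma innermost).
#'
#' @param X standardized descriptor matrix, already restricted to the
#'   concluded descriptor set.
#' @param y response vector.
#' @param folds a \linkS4class{FoldAssignment}.
#' @param grid a \linkS4class{HyperparamGrid}; default
#'   \code{\link{defaultSvrGrid}()}.
#' @return list(C, epsilon, gamma, cvR2, results) where results is the
#'   full score table.
#' @export
tuneSvr <- function(X, y, folds, grid = defaultSvrGrid()) {
  X <- asMatrixX(X)
  res <- list()
  best <- NULL
  for (C in grid@CValues) for (eps in grid@epsilonValues)
    for (g in grid@gammaValues) {
      r2 <- cvTestR2(svrSpec(C = C, epsilon = eps, gamma = g), X, y, folds)
      res[[length(res) + 1L]] <- data.frame(
        C = C, epsilon = eps,
        gamma = if (is.character(g)) g else format(g), cvR2 = r2,
        stringsAsFactors = FALSE)
      if (is.null(best) || r2 > best$cvR2 + 1e-15)
        best <- list(C = C, epsilon = eps, gamma = g, cvR2 = r2)
    }
  best$results <- do.call(rbind, res)
  best
}
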