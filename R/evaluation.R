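#' Coefficient of determination
#'
#' 1 - SS_res/SS_tot against the mean of \code{y}; negative when the
#' predictions do worse than the mean.
#'
#' @param y observed values (length >= 2, non-constant).
#' @param yhat predictions of equal length.
#' @return numeric(1).
#' @export
r2Score <- function(y, yhat) {
  stopIfNot(length(y) == length(yhat), "y and yhat lengths differ")
  stopIfNot(length(y) >= 2L, "need at least 2 observations")
  sst <- sum((y - mean(y))^2)
  stopIfNot(sst > 0, "constant y: r-squared undefined")
  1 - sum((y - yhat)^2) / sst
}

#' Root mean squared error
#'
#' @param y observed values.
#' @param yhat predictions of equal length.
#' @return numeric(1).
#' @export
rmse <- function(y, yhat) {
  stopIfNot(length(y) == length(yhat), "y and yhat lengths differ")
  stopIfNot(length(y) >= 1L, "empty input")
  sqrt(mean((y - yhat)^2))
}

#' Lin's concordance correlation coefficient
#'
#' Agreement with the identity line:
#' 2 cov(y, yhat) / (var(y) + var(yhat) + (mean(y) - mean(yhat))^2),
#' with the n-denominator (population) convention used consistently in
#' both covariance and variances.
#'
#' @param y observed values (length >= 2, non-constant).
#' @param yhat predictions (non-constant).
#' @return numeric(1) in [-1, 1].
#' @export
ccc <- function(y, yhat) {
  stopIfNot(length(y) == length(yhat), "y and yhat lengths differ")
  n <- length(y)
  stopIfNot(n >= 2L, "need at least 2 observations")
  my <- mean(y); mh <- mean(yhat)
  vy <- mean((y - my)^2); vh <- mean((yhat - mh)^2)
  stopIfNot(vy > 0 && vh > 0, "zero variance: CCC undefined")
  cv <- mean((y - my) * (yhat - mh))
  2 * cv / (vy + vh + (my - mh)^2)
}

#' Model specifications for the cross-validation harness
#'
#' A model spec is a deterministic fit/predict pair used by
#' \code{\link{crossValidate}}, \code{\link{tuneSvr}} and the selection
#' routines. \code{mlrSpec} refits OLS on the given descriptors;
#' \code{svrSpec} and \code{gprSpec} do the same with the kernel models;
#' \code{meanSpec} predicts the training mean (a null model useful as a
#' baseline).
#'
#' @param descriptors character vector of descriptor names the spec
#'   restricts itself to (NULL = all columns given to the harness).
#' @param C,epsilon,gamma SVR hyperparameters (see \code{\link{fitSvr}}).
#' @param optimize,restarts,seed GPR settings (see \code{\link{fitGpr}}).
#' @return list with elements \code{fit}, \code{predict}, \code{label}.
#' @name modelSpecs
NULL

subsetCols <- function(X, descriptors) {
  if (is.null(descriptors)) X else {
    miss <- setdiff(descriptors, colnames(X))
    if (length(miss))
      stop("missing descriptor columns: ", paste(miss, collapse = ", "))
    X[, descriptors, drop = FALSE]
  }
}

#' @rdname modelSpecs
#' @export
mlrSpec <- function(descriptors = NULL) {
  list(fit = function(X, y) fitOls(subsetCols(X, descriptors), y),
       predict = function(model, X) predict(model, X),
       label = "mlr")
}

#' @rdname modelSpecs
#' @export
svrSpec <- function(descriptors = NULL, C = 1, epsilon = 0.001,
                    gamma = "auto") {
  list(fit = function(X, y)
         fitSvr(subsetCols(X, descriptors), y, C, epsilon, gamma),
       predict = function(model, X) predict(model, X),
       label = "svr")
}

#' @rdname modelSpecs
#' @export
gprSpec <- function(descriptors = NULL, optimize = TRUE, restarts = 5L,
                    seed = 1L) {
  list(fit = function(X, y)
         fitGpr(subsetCols(X, descriptors), y, optimize = optimize,
                restarts = restarts, seed = seed),
       predict = function(model, X) predict(model, X),
       label = "gpr")
}

#' @rdname modelSpecs
#' @export
meanSpec <- function() {
  list(fit = function(X, y) list(mu = mean(y)),
       predict = function(model, X) rep(model$mu, nrow(X)),
       label = "mean")
}

#' K-fold cross-validation of a model spec
#'
#' For each fold the spec is refitted on the remaining folds and scored
#' (r-squared, RMSE, CCC) on both its training portion and the held-out
#' fold. Aggregates are unweighted means over folds; the pooled
#' out-of-fold statistics are reported alongside as an alternative
#' aggregation mode.
#'
#' @param spec a model spec (see \link{modelSpecs}).
#' @param X descriptor matrix (standardized) or
#'   \linkS4class{DescriptorMatrix}.
#' @param y response vector.
#' @param folds a \linkS4class{FoldAssignment} over the rows of X.
#' @return a \linkS4class{FoldStats}.
#' @export
crossValidate <- function(spec, X, y, folds) {
  if (is(X, "DescriptorMatrix")) X <- X@values
  X <- asMatrixX(X)
  f <- foldOf(folds)
  stopIfNot(length(f) == nrow(X), "folds do not match X")
  sizes <- tabulate(f, nFolds(folds))
  stopIfNot(all(sizes >= 2L), "every fold needs at least 2 observations")
  rows <- vector("list", nFolds(folds))
  pooledPred <- numeric(length(y))
  for (fi in seq_len(nFolds(folds))) {
    test <- which(f == fi)
    train <- which(f != fi)
    model <- spec$fit(X[train, , drop = FALSE], y[train])
    ptr <- spec$predict(model, X[train, , drop = FALSE])
    pte <- spec$predict(model, X[test, , drop = FALSE])
    pooledPred[test] <- pte
    # constant predictions (e.g. a null model) leave CCC undefined: NA
    safeCcc <- function(a, b) tryCatch(ccc(a, b),
                                       error = function(e) NA_real_)
    rows[[fi]] <- data.frame(
      fold = fi,
      trainR2 = r2Score(y[train], ptr), trainRmse = rmse(y[train], ptr),
      trainCcc = safeCcc(y[train], ptr),
      testR2 = r2Score(y[test], pte), testRmse = rmse(y[test], pte),
      testCcc = safeCcc(y[test], pte))
  }
  perFold <- do.call(rbind, rows)
  agg <- list(
    train = c(r2 = mean(perFold$trainR2), rmse = mean(perFold$trainRmse),
              ccc = mean(perFold$trainCcc)),
    test = c(r2 = mean(perFold$testR2), rmse = mean(perFold$testRmse),
             ccc = mean(perFold$testCcc)))
  pooled <- c(r2 = r2Score(y, pooledPred), rmse = rmse(y, pooledPred),
              ccc = ccc(y, pooledPred))
  new("FoldStats", perFold = perFold, aggregate = agg, pooled = pooled)
}

#' Cross-validated test r-squared (fold-averaged)
#'
#' @param spec,X,y,folds as in \code{\link{crossValidate}}.
#' @return numeric(1).
#' @export
cvTestR2 <- function(spec, X, y, folds) {
  unname(crossValidate(spec, X, y, folds)@aggregate$test["r2"])
}

#' Permutation importance of descriptor columns
#'
#' For an already-fitted model, each column of X is permuted
#' \code{nRepeats} times (seeded) and the importance is the mean decrease
#' of r-squared relative to the unpermuted baseline; the model is never
#' refitted. Values above 1 occur when permuting drives r-squared
#' negative.
#'
#' @param model a fitted model with a \code{predict} method
#'   (\linkS4class{LinearModel}, \linkS4class{SvrModel},
#'   \linkS4class{GprModel}).
#' @param X matrix the model was fitted on (or a superset of columns).
#' @param y response vector.
#' @param nRepeats permutations per column (default 30).
#' @param seed RNG seed (mandatory).
#' @return an \linkS4class{ImportanceTable}.
#' @export
permutationImportance <- function(model, X, y, nRepeats = 30L, seed) {
  stopIfNot(nRepeats >= 1L, "nRepeats must be >= 1")
  if (is(X, "DescriptorMatrix")) X <- X@values
  X <- asMatrixX(X)
  baseline <- r2Score(y, predict(model, X))
  n <- nrow(X)
  cols <- colnames(X)
  imp <- sdv <- numeric(length(cols))
  for (j in seq_along(cols)) {
    # per-column seed derived from the column's own name, so a column's
    # importance is invariant to relabeling or reordering of the others
    drops <- withSeed(columnSeed(seed, cols[j]), {
      vapply(seq_len(nRepeats), function(r) {
        Xp <- X
        Xp[, j] <- X[sample.int(n), j]
        baseline - r2Score(y, predict(model, Xp))
      }, numeric(1))
    })
    imp[j] <- mean(drops)
    sdv[j] <- stats::sd(drops)
  }
  new("ImportanceTable",
      table = data.frame(descriptor = cols, importance = imp, sd = sdv,
                         stringsAsFactors = FALSE),
      nRepeats = as.integer(nRepeats), seed = as.integer(seed))
}
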