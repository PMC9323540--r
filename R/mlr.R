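#' Ordinary least squares fit on descriptor columns
#'
#' Minimizes squared error over an intercept plus the given columns; on
#' standardized descriptors the intercept equals mean(y).
#'
#' @param X numeric matrix of descriptor columns (named).
#' @param y response vector.
#' @return a \linkS4class{LinearModel}.
#' @examples
#' X <- scale(matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a","b","c"))))
#' y <- 2 * X[, "a"] - X[, "c"] + rnorm(10, sd = 0.1)
#' fitOls(X, y)
#' @export
fitOls <- function(X, y) {
  if (is.null(X) || (!is.null(dim(X)) && ncol(X) == 0L)) {
    # intercept-only model
    return(new("LinearModel", descriptorNames = character(0),
               beta0 = mean(y), betas = numeric(0),
               nTrain = length(y)))
  }
  X <- asMatrixX(X)
  n <- nrow(X); k <- ncol(X)
  stopIfNot(length(y) == n, "length(y) must match nrow(X)")
  stopIfNot(n > k + 1L, "need n > k + 1 (n=%d, k=%d)", n, k)
  D <- cbind(`(Intercept)` = 1, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    dep <- colnames(D)[qrD$pivot[(qrD$rank + 1L):ncol(D)]]
    stop("rank-deficient design; dependent columns: ",
         paste(dep, collapse = ", "))
  }
  beta <- qr.coef(qrD, y)
  new("LinearModel", descriptorNames = colnames(X),
      beta0 = unname(beta[1L]), betas = unname(beta[-1L]),
      nTrain = as.integer(n))
}

#' Predict from a fitted linear model
#'
#' @param object a \linkS4class{LinearModel}.
#' @param newdata numeric matrix or \linkS4class{DescriptorMatrix}
#'   containing the model's descriptor columns.
#' @param ... ignored.
#' @return numeric vector of predictions.
#' @export
setMethod("predict", "LinearModel", function(object, newdata, ...) {
  X <- if (is(newdata, "DescriptorMatrix")) newdata@values else
    asMatrixX(newdata)
  if (length(object@descriptorNames) == 0L)
    return(rep(object@beta0, nrow(X)))
  miss <- setdiff(object@descriptorNames, colnames(X))
  if (length(miss))
    stop("missing descriptor columns: ", paste(miss, collapse = ", "))
  drop(object@beta0 +
         X[, object@descriptorNames, drop = FALSE] %*% object@betas)
})

#' Orthogonal matching pursuit descriptor selection
#'
#' Greedy sparse regression: starting from the intercept-only residual,
#' repeatedly add the descriptor most correlated (absolute Pearson) with
#' the current residual and refit full OLS on the active set, until k
#' descriptors are selected. A descriptor is never added twice.
#'
#' @param X standardized descriptor matrix.
#' @param y response vector.
#' @param k number of descriptors to select (0 gives the intercept-only
#'   model).
#' @return a \linkS4class{LinearModel} with descriptors in selection order.
#' @export
ompSelect <- function(X, y, k) {
  X <- asMatrixX(X)
  stopIfNot(k <= ncol(X), "k (%d) exceeds available descriptors (%d)",
            k, ncol(X))
  active <- character(0)
  model <- fitOls(NULL, y)
  residual <- y - mean(y)
  for (step in seq_len(k)) {
    if (stats::sd(residual) < 1e-12 * max(1, stats::sd(y))) {
      warning(sprintf(
        "residual numerically zero after %d descriptors; returning smaller model",
        length(active)))
      break
    }
    pool <- setdiff(colnames(X), active)
    cors <- abs(pearson(X[, pool, drop = FALSE], residual))
    best <- pool[which.max(cors)]
    active <- c(active, best)
    model <- fitOls(X[, active, drop = FALSE], y)
    residual <- y - predict(model, X)
  }
  model
}

#' Expulsion search around orthogonal matching pursuit
#'
#' Widens OMP's search space: run OMP on the current descriptor pool and
#' record the candidate model; while the pool still holds a descriptor
#' whose absolute Pearson correlation with y is at least
#' \code{corrThreshold}, expel that descriptor (the argmax) from the pool
#' and rerun OMP. Among the recorded same-size candidates the one with the
#' highest cross-validated test r-squared wins (ties to the earliest
#' round). Expelled descriptors leave only the selection pool; each
#' candidate is always evaluated on its own descriptors.
#'
#' @param X standardized descriptor matrix.
#' @param y response vector.
#' @param k model size per OMP run.
#' @param folds a \linkS4class{FoldAssignment} for candidate evaluation.
#' @param corrThreshold expulsion stops once max |corr(X_j, y)| drops
#'   below this (default 0.4).
#' @param criterion "cv" scores candidates by cross-validated test
#'   r-squared (default); "train" uses training r-squared on the full data.
#' @return list with the winning \code{model} (a
#'   \linkS4class{LinearModel}), its \code{cvR2}, and the
#'   \linkS4class{SelectionTrace}.
#' @export
expulsionSearch <- function(X, y, k, folds, corrThreshold = 0.4,
                            criterion = c("cv", "train")) {
  criterion <- match.arg(criterion)
  X <- asMatrixX(X)
  pool <- colnames(X)
  rounds <- list()
  stopReason <- NULL
  repeat {
    candidate <- ompSelect(X[, pool, drop = FALSE], y, min(k, length(pool)))
    score <- if (criterion == "cv") {
      cv <- crossValidate(mlrSpec(descriptorNames(candidate)), X, y, folds)
      unname(cv@aggregate$test["r2"])
    } else {
      r2Score(y, predict(candidate, X))
    }
    cors <- abs(pearson(X[, pool, drop = FALSE], y))
    expelled <- NA_character_
    if (max(cors) >= corrThreshold) {
      expelled <- pool[which.max(cors)]
      pool <- setdiff(pool, expelled)
    }
    rounds[[length(rounds) + 1L]] <-
      list(expelled = expelled, model = candidate, cvR2 = score)
    if (is.na(expelled)) { stopReason <- "correlation below threshold"; break }
    if (length(pool) == 0L) { stopReason <- "pool exhausted"; break }
  }
  scores <- vapply(rounds, function(r) r$cvR2, numeric(1))
  best <- which.max(scores)  # which.max takes the earliest maximum
  list(model = rounds[[best]]$model, cvR2 = scores[best],
       trace = new("SelectionTrace", rounds = rounds,
                   stopReason = stopReason))
}

#' Choose the model size by the 20 percent error-improvement rule
#'
#' Starting from one descriptor, a model with one more descriptor is
#' accepted only while it corrects at least \code{improvementFraction} of
#' the previous prediction error, with error measured as 1 - r-squared:
#' accept k+1 iff (err_k - err_{k+1}) / err_k >= 0.20.
#'
#' @param candidateBuilder deterministic function(k) returning
#'   \code{list(model = ..., cvError = 1 - r2)}.
#' @param kMax largest size to consider.
#' @param improvementFraction acceptance fraction (default 0.20).
#' @return list with the chosen \code{model}, its size \code{k}, and the
#'   per-size \code{errors} examined.
#' @export
chooseModelSize <- function(candidateBuilder, kMax,
                            improvementFraction = 0.20) {
  stopIfNot(kMax >= 1, "kMax must be >= 1")
  cur <- candidateBuilder(1L)
  errors <- cur$cvError
  k <- 1L
  while (k < kMax) {
    if (cur$cvError <= 0) break  # nothing left to correct
    nxt <- candidateBuilder(k + 1L)
    errors <- c(errors, nxt$cvError)
    if ((cur$cvError - nxt$cvError) / cur$cvError >=
        improvementFraction - 1e-12) {
      cur <- nxt
      k <- k + 1L
    } else break
  }
  list(model = cur$model, k = k, errors = errors)
}

#' Full linear-model selection: expulsion search plus the size rule
#'
#' Convenience wrapper combining \code{\link{expulsionSearch}} at each
#' size with \code{\link{chooseModelSize}}.
#'
#' @param X standardized descriptor matrix.
#' @param y response vector.
#' @param folds a \linkS4class{FoldAssignment}.
#' @param kMax largest model size considered (default 8).
#' @param corrThreshold expulsion threshold (default 0.4).
#' @param improvementFraction size-rule fraction (default 0.20).
#' @return list(model, k, errors, cvR2).
#' @export
selectMlr <- function(X, y, folds, kMax = 8L, corrThreshold = 0.4,
                      improvementFraction = 0.20) {
  builder <- function(k) {
    res <- expulsionSearch(X, y, k, folds, corrThreshold)
    list(model = res$model, cvError = 1 - res$cvR2, cvR2 = res$cvR2)
  }
  ch <- chooseModelSize(builder, kMax, improvementFraction)
  ch$cvR2 <- 1 - ch$errors[ch$k]
  ch
}

#' Export a fitted model to JSON
#'
#' Writes descriptor names, coefficients or kernel parameters, and (when a
#' standardized \linkS4class{DescriptorMatrix} is supplied) the column
#' means/sds needed to predict for new cations, plus free-form provenance.
#'
#' @param model a \linkS4class{LinearModel}, \linkS4class{SvrModel} or
#'   \linkS4class{GprModel}.
#' @param path output file.
#' @param descriptorMatrix optional standardized
#'   \linkS4class{DescriptorMatrix} whose statistics are embedded.
#' @param provenance named list recorded verbatim.
#' @return \code{path}, invisibly.
#' @export
exportModelJson <- function(model, path, descriptorMatrix = NULL,
                            provenance = list()) {
  doc <- list(class = class(model)[1L],
              descriptors = descriptorNames(model))
  if (is(model, "LinearModel")) {
    doc$intercept <- model@beta0
    doc$coefficients <- as.list(stats::setNames(model@betas,
                                                model@descriptorNames))
  } else if (is(model, "SvrModel")) {
    doc$C <- model@cost; doc$epsilon <- model@epsilon
    doc$gamma <- model@gamma; doc$gammaValue <- model@gammaValue
    doc$intercept <- model@intercept
    doc$supportIndices <- model@supportIndices
    doc$alphas <- model@alphas
  } else if (is(model, "GprModel")) {
    doc$kernelParams <- list(sigma0 = model@sigma0,
                             noiseLevel = model@noiseLevel,
                             lengthScale = model@lengthScale)
    doc$logMarginalLikelihood <- model@logMarginalLikelihood
    doc$trainRowIds <- rownames(model@X)
  } else stop("unsupported model class: ", class(model)[1L])
  if (!is.null(descriptorMatrix) && isStandardized(descriptorMatrix)) {
    nm <- descriptorNames(model)
    idx <- match(nm, descriptorNames(descriptorMatrix))
    doc$standardization <- list(
      means = as.list(stats::setNames(descriptorMatrix@columnMeans[idx], nm)),
      sds = as.list(stats::setNames(descriptorMatrix@columnSds[idx], nm)))
  }
  if (length(provenance)) doc$provenance <- provenance
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
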