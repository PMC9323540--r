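#' @import methods
NULL

#' PropertySeries: one solute's partition-coefficient series
#'
#' Holds the experimental gas--ionic-liquid partition coefficients
#' (log10 K at 298 K) of one solute across a series of ionic-liquid
#' cations, together with each cation's identifier and SMILES.
#'
#' @slot solute character(1), e.g. "hexane".
#' @slot records data.frame with columns \code{cationId}, \code{smiles},
#'   \code{logK}, in input order.
#' @export
setClass("PropertySeries",
  slots = c(solute = "character", records = "data.frame"))

setValidity("PropertySeries", function(object) {
  r <- object@records
  msgs <- character(0)
  need <- c("cationId", "smiles", "logK")
  if (!all(need %in% names(r)))
    return(paste("records must have columns", paste(need, collapse = ", ")))
  if (nrow(r) < 2L) msgs <- c(msgs, "a series needs at least 2 records")
  if (anyDuplicated(r$cationId))
    msgs <- c(msgs, sprintf("duplicate cation id '%s'",
                            r$cationId[duplicated(r$cationId)][1L]))
  if (!is.numeric(r$logK) || any(!is.finite(r$logK)))
    msgs <- c(msgs, "all logK values must be finite numbers")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PropertySeries
#'
#' @param solute solute name (free text; hexane, cyclohexane and benzene in
#'   the motivating data).
#' @param cationId character vector of unique cation labels.
#' @param smiles character vector of cation SMILES (charge included).
#' @param logK numeric vector of log10 partition coefficients.
#' @return a \linkS4class{PropertySeries}.
#' @examples
#' ps <- PropertySeries("hexane", c("a", "b", "c"), c("C", "CC", "CCC"),
#'                      c(0.3, 1.1, 2.0))
#' logK(ps)
#' @export
PropertySeries <- function(solute, cationId, smiles, logK) {
  new("PropertySeries", solute = as.character(solute)[1L],
      records = data.frame(cationId = as.character(cationId),
                           smiles = as.character(smiles),
                           logK = as.numeric(logK),
                           stringsAsFactors = FALSE))
}

#' DescriptorMatrix: cations-by-descriptors numeric table
#'
#' The X matrix of the QSPR workflow: one row per cation, one column per
#' 2D molecular descriptor, plus its standardization state. When
#' standardized, the per-column means and sample standard deviations of the
#' original values are retained so the same transform can be applied to new
#' cations.
#'
#' @slot values numeric matrix with cation ids as rownames and unique
#'   descriptor names as colnames; NA marks a failed engine value (only
#'   before pruning).
#' @slot standardized logical(1).
#' @slot columnMeans,columnSds numeric, per column when standardized.
#' @slot removalLog data.frame (\code{descriptor}, \code{reason}) filled by
#'   \code{\link{pruneDescriptors}}.
#' @export
setClass("DescriptorMatrix",
  slots = c(values = "matrix", standardized = "logical",
            columnMeans = "numeric", columnSds = "numeric",
            removalLog = "data.frame"))

setValidity("DescriptorMatrix", function(object) {
  v <- object@values
  msgs <- character(0)
  if (!is.numeric(v)) return("values must be numeric")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msgs <- c(msgs, "descriptor names must be present and unique")
  if (is.null(rownames(v))) msgs <- c(msgs, "row ids must be present")
  if (isTRUE(object@standardized)) {
    if (anyNA(v)) msgs <- c(msgs, "a standardized matrix cannot contain NA")
    else {
      mu <- colMeans(v)
      sdv <- apply(v, 2L, stats::sd)
      if (any(abs(mu) > 1e-9) || any(abs(sdv - 1) > 1e-9))
        msgs <- c(msgs,
          "standardized columns must have mean 0 and sd 1 (tol 1e-9)")
    }
    if (length(object@columnMeans) != ncol(v) ||
        length(object@columnSds) != ncol(v))
      msgs <- c(msgs, "columnMeans/columnSds must match column count")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a DescriptorMatrix
#'
#' @param values numeric matrix (rownames = cation ids, colnames =
#'   descriptor names).
#' @param standardized logical(1); use \code{\link{standardizeDescriptors}}
#'   rather than setting this by hand.
#' @param columnMeans,columnSds original column statistics (standardized
#'   matrices only).
#' @param removalLog pruning log, normally left empty.
#' @return a \linkS4class{DescriptorMatrix}.
#' @export
DescriptorMatrix <- function(values, standardized = FALSE,
                             columnMeans = numeric(0),
                             columnSds = numeric(0),
                             removalLog = emptyRemovalLog()) {
  values <- asMatrixX(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("obs%03d", seq_len(nrow(values)))
  new("DescriptorMatrix", values = values, standardized = standardized,
      columnMeans = columnMeans, columnSds = columnSds,
      removalLog = removalLog)
}

emptyRemovalLog <- function() {
  data.frame(descriptor = character(0), reason = character(0),
             stringsAsFactors = FALSE)
}

#' FoldAssignment: deterministic stratified k-fold partition
#'
#' Observations are ranked by ascending response; the observation of
#' zero-based rank j belongs to fold (j mod nFolds) + 1, so every fold
#' spans the whole response range ("every tenth cation" at the default 10).
#'
#' @slot nFolds integer(1).
#' @slot foldOf integer vector, fold index (1-based) per observation in
#'   input order.
#' @export
setClass("FoldAssignment", slots = c(nFolds = "integer", foldOf = "integer"))

setValidity("FoldAssignment", function(object) {
  f <- object@foldOf
  k <- object@nFolds
  if (length(k) != 1L || k < 2L) return("nFolds must be a single integer >= 2")
  if (any(f < 1L | f > k)) return("fold indices out of range")
  sizes <- tabulate(f, nbins = k)
  if (diff(range(sizes)) > 1L) return("fold sizes must differ by at most 1")
  TRUE
})

#' LinearModel: a fitted sparse multiple linear regression
#'
#' @slot descriptorNames selected descriptors, in selection order.
#' @slot beta0 intercept.
#' @slot betas coefficients on (standardized) descriptor columns.
#' @slot nTrain number of training observations.
#' @export
setClass("LinearModel",
  slots = c(descriptorNames = "character", beta0 = "numeric",
            betas = "numeric", nTrain = "integer"))

setValidity("LinearModel", function(object) {
  if (length(object@betas) != length(object@descriptorNames))
    return("one coefficient per descriptor required")
  if (!all(is.finite(c(object@beta0, object@betas))))
    return("coefficients must be finite")
  TRUE
})

#' SelectionTrace: record of an expulsion search
#'
#' @slot rounds list; each element has \code{expelled} (descriptor removed
#'   from the pool at the end of the round, or NA on the final round),
#'   \code{model} (the round's OMP candidate), \code{cvR2}.
#' @slot stopReason character(1).
#' @export
setClass("SelectionTrace",
  slots = c(rounds = "list", stopReason = "character"))

#' SvrModel: epsilon-insensitive support vector regression with RBF kernel
#'
#' @slot descriptorNames descriptors the model uses.
#' @slot cost,epsilon penalty C and tube half-width.
#' @slot gamma kernel scale as given (number or token "auto"/"scale").
#' @slot gammaValue resolved numeric kernel scale.
#' @slot supportIndices training-row indices of the support vectors.
#' @slot alphas signed dual coefficients, one per support vector.
#' @slot intercept bias term b.
#' @slot fit underlying solver object used for prediction.
#' @export
setClass("SvrModel",
  slots = c(descriptorNames = "character", cost = "numeric",
            epsilon = "numeric", gamma = "ANY", gammaValue = "numeric",
            supportIndices = "integer", alphas = "numeric",
            intercept = "numeric", fit = "ANY"))

setValidity("SvrModel", function(object) {
  if (length(object@alphas) != length(object@supportIndices))
    return("one dual coefficient per support vector required")
  if (length(object@cost) == 1L &&
      any(abs(object@alphas) > object@cost * (1 + 1e-8)))
    return("dual coefficients must satisfy |alpha_i| <= C")
  TRUE
})

#' GprModel: Gaussian process regression with a composite kernel
#'
#' Kernel: k(x, x') = sigma0^2 + x.x' + exp(-||x - x'||^2 / (2 l^2)),
#' plus white noise of variance \code{noiseLevel} on the training diagonal.
#'
#' @slot descriptorNames descriptors the model uses.
#' @slot X,y training inputs (standardized) and targets.
#' @slot sigma0,noiseLevel,lengthScale kernel hyperparameters.
#' @slot logMarginalLikelihood value at the fitted hyperparameters.
#' @slot L,alpha Cholesky factor of K(X,X)+noise and K^{-1} y cache.
#' @export
setClass("GprModel",
  slots = c(descriptorNames = "character", X = "matrix", y = "numeric",
            sigma0 = "numeric", noiseLevel = "numeric",
            lengthScale = "numeric", logMarginalLikelihood = "numeric",
            L = "matrix", alpha = "numeric"))

setValidity("GprModel", function(object) {
  if (nrow(object@X) != length(object@y))
    return("X rows must match length of y")
  if (object@noiseLevel < 0 || object@lengthScale <= 0)
    return("noiseLevel must be >= 0 and lengthScale > 0")
  TRUE
})

#' HyperparamGrid: SVR tuning grid
#'
#' @slot CValues,epsilonValues positive numerics.
#' @slot gammaValues list of positive numbers and/or tokens "auto", "scale".
#' @export
setClass("HyperparamGrid",
  slots = c(CValues = "numeric", epsilonValues = "numeric",
            gammaValues = "list"))

setValidity("HyperparamGrid", function(object) {
  if (!length(object@CValues) || !length(object@epsilonValues) ||
      !length(object@gammaValues)) return("grid axes must be non-empty")
  if (any(object@CValues <= 0) || any(object@epsilonValues <= 0))
    return("C and epsilon grid values must be positive")
  for (g in object@gammaValues) {
    ok <- (is.numeric(g) && g > 0) ||
      (is.character(g) && g %in% c("auto", "scale"))
    if (!ok) return("gamma values must be positive numbers, 'auto' or 'scale'")
  }
  TRUE
})

#' Construct a HyperparamGrid
#'
#' @param CValues,epsilonValues positive numeric vectors.
#' @param gammaValues list (or vector) of positive numbers and/or the
#'   tokens "auto" and "scale".
#' @return a \linkS4class{HyperparamGrid}.
#' @export
HyperparamGrid <- function(CValues, epsilonValues, gammaValues) {
  new("HyperparamGrid", CValues = as.numeric(CValues),
      epsilonValues = as.numeric(epsilonValues),
      gammaValues = as.list(gammaValues))
}

#' FoldStats: cross-validation statistics
#'
#' @slot perFold data.frame with one row per fold: train/test r2, RMSE, CCC.
#' @slot aggregate list with \code{train} and \code{test} named triples,
#'   unweighted means over folds.
#' @slot pooled named triple computed on pooled out-of-fold predictions
#'   (alternative aggregation mode).
#' @export
setClass("FoldStats",
  slots = c(perFold = "data.frame", aggregate = "list", pooled = "numeric"))

#' ImportanceTable: permutation importances
#'
#' @slot table data.frame (\code{descriptor}, \code{importance},
#'   \code{sd}) with the mean decrease in r-squared per permuted column.
#' @slot nRepeats,seed permutation settings.
#' @export
setClass("ImportanceTable",
  slots = c(table = "data.frame", nRepeats = "integer", seed = "integer"))

#' InfluenceTable: leverage / residual / Cook's distance diagnostics
#'
#' @slot table per-observation data.frame: id, leverage, residual,
#'   stdResidual, cooksD and the flag columns moderateLeverage,
#'   highLeverage, moderateResidual, highResidual, influential, undefined.
#' @slot sigma2 residual variance estimate e'e/(n-k-1).
#' @slot hCrit3,hCrit2 high (3(k+1)/n) and moderate (2(k+1)/n by default)
#'   leverage thresholds.
#' @slot k,n model size and sample size.
#' @export
setClass("InfluenceTable",
  slots = c(table = "data.frame", sigma2 = "numeric", hCrit3 = "numeric",
            hCrit2 = "numeric", k = "integer", n = "integer"))

#' SyntheticSpec: settings for the planted-signal data generator
#'
#' @slot n,p observations and base descriptor count.
#' @slot kTrue planted signal size.
#' @slot betaTrue planted standardized coefficients (length kTrue).
#' @slot targetR2 population r-squared the noise is calibrated to.
#' @slot nCollinearDecoys,nConstantDecoys decoy columns appended to the
#'   base matrix.
#' @slot nOutliers rows available to \code{\link{injectAnomalies}}.
#' @slot rho within-block correlation of the base matrix.
#' @slot blockSize columns per correlated block.
#' @slot interceptTrue baseline added to y.
#' @slot seed mandatory RNG seed.
#' @export
setClass("SyntheticSpec",
  slots = c(n = "integer", p = "integer", kTrue = "integer",
            betaTrue = "numeric", targetR2 = "numeric",
            nCollinearDecoys = "integer", nConstantDecoys = "integer",
            nOutliers = "integer", rho = "numeric", blockSize = "integer",
            interceptTrue = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msgs <- character(0)
  if (object@kTrue > object@p) msgs <- c(msgs, "kTrue must be <= p")
  if (length(object@betaTrue) != object@kTrue)
    msgs <- c(msgs, "betaTrue must have length kTrue")
  if (object@targetR2 <= 0 || object@targetR2 > 1)
    msgs <- c(msgs, "targetR2 must lie in (0, 1]")
  if (object@rho < 0 || object@rho >= 1)
    msgs <- c(msgs, "rho must lie in [0, 1)")
  if (object@kTrue > object@p %/% object@blockSize)
    msgs <- c(msgs, "need at least kTrue blocks (p/blockSize)")
  if (length(msgs)) msgs else TRUE
})
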