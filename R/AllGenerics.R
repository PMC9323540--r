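#' @include AllClasses.R
NULL

#' Accessors for the core classes
#'
#' \code{logK}, \code{cationIds}, \code{solute} read a
#' \linkS4class{PropertySeries}; \code{descriptorNames}, \code{rowIds},
#' \code{isStandardized}, \code{removalLog} read a
#' \linkS4class{DescriptorMatrix}; \code{nFolds} and \code{foldOf} read a
#' \linkS4class{FoldAssignment}.
#'
#' @param x the object.
#' @return the corresponding vector, flag or data.frame.
#' @name accessors
#' @aliases logK cationIds solute descriptorNames rowIds isStandardized
#'   removalLog nFolds foldOf
NULL

#' @rdname accessors
#' @export
setGeneric("logK", function(x) standardGeneric("logK"))
#' @rdname accessors
#' @export
setGeneric("cationIds", function(x) standardGeneric("cationIds"))
#' @rdname accessors
#' @export
setGeneric("solute", function(x) standardGeneric("solute"))
#' @rdname accessors
#' @export
setGeneric("descriptorNames", function(x) standardGeneric("descriptorNames"))
#' @rdname accessors
#' @export
setGeneric("rowIds", function(x) standardGeneric("rowIds"))
#' @rdname accessors
#' @export
setGeneric("isStandardized", function(x) standardGeneric("isStandardized"))
#' @rdname accessors
#' @export
setGeneric("removalLog", function(x) standardGeneric("removalLog"))
#' @rdname accessors
#' @export
setGeneric("nFolds", function(x) standardGeneric("nFolds"))
#' @rdname accessors
#' @export
setGeneric("foldOf", function(x) standardGeneric("foldOf"))

#' @rdname accessors
setMethod("logK", "PropertySeries", function(x) {
  stats::setNames(x@records$logK, x@records$cationId)
})
#' @rdname accessors
setMethod("cationIds", "PropertySeries", function(x) x@records$cationId)
#' @rdname accessors
setMethod("solute", "PropertySeries", function(x) x@solute)
#' @rdname accessors
setMethod("descriptorNames", "DescriptorMatrix",
          function(x) colnames(x@values))
#' @rdname accessors
setMethod("descriptorNames", "LinearModel", function(x) x@descriptorNames)
#' @rdname accessors
setMethod("descriptorNames", "SvrModel", function(x) x@descriptorNames)
#' @rdname accessors
setMethod("descriptorNames", "GprModel", function(x) x@descriptorNames)
#' @rdname accessors
setMethod("rowIds", "DescriptorMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("isStandardized", "DescriptorMatrix", function(x) x@standardized)
#' @rdname accessors
setMethod("removalLog", "DescriptorMatrix", function(x) x@removalLog)
#' @rdname accessors
setMethod("nFolds", "FoldAssignment", function(x) x@nFolds)
#' @rdname accessors
setMethod("foldOf", "FoldAssignment", function(x) x@foldOf)

#' @export
setMethod("length", "PropertySeries", function(x) nrow(x@records))

#' Extract the numeric matrix from a DescriptorMatrix
#' @param x a \linkS4class{DescriptorMatrix}.
#' @param ... ignored.
#' @return the underlying numeric matrix.
#' @export
setMethod("as.matrix", "DescriptorMatrix", function(x, ...) x@values)

#' @export
setMethod("dim", "DescriptorMatrix", function(x) dim(x@values))

#' Coefficients of a fitted linear QSPR model
#' @param object a \linkS4class{LinearModel}.
#' @param ... ignored.
#' @return named numeric vector, intercept first.
#' @export
setMethod("coef", "LinearModel", function(object, ...) {
  stats::setNames(c(object@beta0, object@betas),
                  c("(Intercept)", object@descriptorNames))
})

setMethod("show", "PropertySeries", function(object) {
  lk <- object@records$logK
  cat(sprintf("PropertySeries: %s, %d cations, logK in [%.3f, %.3f]\n",
              object@solute, nrow(object@records), min(lk), max(lk)))
})

setMethod("show", "DescriptorMatrix", function(object) {
  cat(sprintf("DescriptorMatrix: %d cations x %d descriptors (%s)\n",
              nrow(object@values), ncol(object@values),
              if (object@standardized) "standardized" else "raw"))
  if (nrow(object@removalLog))
    cat(sprintf("  pruning removed %d descriptors\n",
                nrow(object@removalLog)))
})

setMethod("show", "FoldAssignment", function(object) {
  cat(sprintf("FoldAssignment: %d observations in %d folds (sizes %s)\n",
              length(object@foldOf), object@nFolds,
              paste(tabulate(object@foldOf, object@nFolds),
                    collapse = ",")))
})

setMethod("show", "LinearModel", function(object) {
  cat(sprintf("LinearModel: %d descriptors, n = %d\n",
              length(object@betas), object@nTrain))
  print(round(coef(object), 4))
})

setMethod("show", "SvrModel", function(object) {
  cat(sprintf(
    "SvrModel: %d descriptors, %d support vectors, C=%g, eps=%g, gamma=%s\n",
    length(object@descriptorNames), length(object@supportIndices),
    object@cost, object@epsilon,
    if (is.character(object@gamma)) object@gamma
    else format(object@gamma)))
})

setMethod("show", "GprModel", function(object) {
  cat(sprintf(
    paste0("GprModel: %d descriptors, n = %d; sigma0=%.4g, ",
           "noiseLevel=%.4g, lengthScale=%.4g (LML %.3f)\n"),
    length(object@descriptorNames), length(object@y), object@sigma0,
    object@noiseLevel, object@lengthScale, object@logMarginalLikelihood))
})

setMethod("show", "FoldStats", function(object) {
  a <- object@aggregate
  cat(sprintf(
    "FoldStats (%d folds): train r2 %.3f rmse %.3f ccc %.3f | test r2 %.3f rmse %.3f ccc %.3f\n",
    nrow(object@perFold), a$train["r2"], a$train["rmse"], a$train["ccc"],
    a$test["r2"], a$test["rmse"], a$test["ccc"]))
})

setMethod("show", "ImportanceTable", function(object) {
  cat(sprintf("ImportanceTable (%d repeats, seed %d):\n",
              object@nRepeats, object@seed))
  print(transform(object@table, importance = signif(importance, 3),
                  sd = signif(sd, 3)))
})

setMethod("show", "InfluenceTable", function(object) {
  t <- object@table
  cat(sprintf(
    "InfluenceTable: n=%d, k=%d, h*3=%.4f; high leverage %d, |r|>2 %d, D>1 %d\n",
    object@n, object@k, object@hCrit3, sum(t$highLeverage),
    sum(t$moderateResidual), sum(t$influential)))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: n=%d, p=%d (+%d collinear, +%d constant decoys), kTrue=%d, target r2=%.2f, rho=%.2f, seed=%d\n",
    object@n, object@p, object@nCollinearDecoys, object@nConstantDecoys,
    object@kTrue, object@targetR2, object@rho, object@seed))
})
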