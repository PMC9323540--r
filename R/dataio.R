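#' Read a property series from delimited text
#'
#' Expects a header with columns for the cation identifier, its SMILES and
#' the experimental log K (column names configurable). Record order is
#' preserved.
#'
#' @param path file path.
#' @param solute solute name stored in the series; defaults to the file
#'   name without extension.
#' @param sep field separator ("," for CSV, "\t" for TSV).
#' @param idCol,smilesCol,logKCol column names in the header.
#' @return a \linkS4class{PropertySeries}.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,smiles,logK", "a,C,0.3", "b,CC,1.1"), f)
#' readSeries(f, solute = "hexane")
#' @export
readSeries <- function(path, solute = NULL, sep = ",",
                       idCol = "id", smilesCol = "smiles",
                       logKCol = "logK") {
  stopIfNot(file.exists(path), "file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "\"")
  if (nrow(df) == 0L) stop("no records in ", path)
  for (col in c(idCol, smilesCol, logKCol))
    stopIfNot(col %in% names(df), "missing column '%s' in %s", col, path)
  lk <- suppressWarnings(as.numeric(df[[logKCol]]))
  bad <- which(!is.finite(lk))
  if (length(bad))
    stop(sprintf("unparseable logK '%s' at row %d of %s",
                 df[[logKCol]][bad[1L]], bad[1L], path))
  dup <- which(duplicated(df[[idCol]]))
  if (length(dup))
    stop(sprintf("duplicate id '%s' at row %d of %s",
                 df[[idCol]][dup[1L]], dup[1L], path))
  if (is.null(solute))
    solute <- tools::file_path_sans_ext(basename(path))
  PropertySeries(solute, df[[idCol]], df[[smilesCol]], lk)
}

#' Write a property series to delimited text
#'
#' @param series a \linkS4class{PropertySeries}.
#' @param path output file.
#' @param sep field separator.
#' @return \code{path}, invisibly.
#' @export
writeSeries <- function(series, path, sep = ",") {
  df <- series@records
  names(df) <- c("id", "smiles", "logK")
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Compute a descriptor matrix through an external engine adapter
#'
#' The descriptor calculation itself is delegated to \code{engine}, a
#' function taking the vector of SMILES and returning one row of numeric
#' descriptor values per molecule (matrix or data.frame with named
#' columns). This function fixes the matrix contract: rows follow the
#' series, non-finite engine outputs become NA (to be handled by
#' \code{\link{pruneDescriptors}}), and engine failures are reported with
#' the offending cation.
#'
#' @param series a \linkS4class{PropertySeries}.
#' @param engine function(smiles character vector) -> numeric
#'   matrix/data.frame with named descriptor columns.
#' @return an unstandardized \linkS4class{DescriptorMatrix}.
#' @export
computeDescriptors <- function(series, engine) {
  stopIfNot(is.function(engine), "'engine' must be a function")
  sm <- series@records$smiles
  out <- tryCatch(engine(sm), error = function(e) e)
  if (inherits(out, "error")) {
    # rerun molecule-by-molecule to name the culprit
    for (i in seq_along(sm)) {
      ok <- tryCatch({ engine(sm[i]); TRUE }, error = function(e) FALSE)
      if (!ok) stop(sprintf(
        "descriptor engine failed for cation '%s' (SMILES '%s'): %s",
        series@records$cationId[i], sm[i], conditionMessage(out)))
    }
    stop("descriptor engine failed: ", conditionMessage(out))
  }
  m <- as.matrix(as.data.frame(out))
  storage.mode(m) <- "double"
  stopIfNot(nrow(m) == length(sm),
            "engine returned %d rows for %d cations", nrow(m), length(sm))
  m[!is.finite(m)] <- NA_real_
  rownames(m) <- series@records$cationId
  DescriptorMatrix(m, standardized = FALSE)
}

#' Prune missing-value, constant and collinear descriptors
#'
#' Three passes, each logged per removed column: (1) any column containing
#' NA is dropped ("missing"); (2) zero-variance columns are dropped
#' ("constant"); (3) scanning the surviving columns in input order, a
#' column whose absolute Pearson correlation with an already-retained
#' column reaches \code{collinearityThreshold} is dropped ("collinear
#' with <kept>") — so the first column of each collinear set survives.
#'
#' @param m an unstandardized \linkS4class{DescriptorMatrix}.
#' @param collinearityThreshold absolute Pearson r in (0, 1] at or above
#'   which a later column is considered redundant; default 0.95.
#' @return the pruned \linkS4class{DescriptorMatrix}; the removal log is
#'   available through \code{\link{removalLog}}.
#' @export
pruneDescriptors <- function(m, collinearityThreshold = 0.95) {
  stopIfNot(!isStandardized(m), "prune before standardizing")
  stopIfNot(collinearityThreshold > 0 && collinearityThreshold <= 1,
            "collinearityThreshold must be in (0, 1]")
  v <- m@values
  log <- list()
  hasNA <- colnames(v)[colSums(is.na(v)) > 0L]
  for (d in hasNA) log[[d]] <- "missing"
  keep <- setdiff(colnames(v), hasNA)
  v <- v[, keep, drop = FALSE]
  vars <- apply(v, 2L, stats::var)
  const <- colnames(v)[vars == 0]
  for (d in const) log[[d]] <- "constant"
  v <- v[, setdiff(colnames(v), const), drop = FALSE]
  if (ncol(v) >= 2L) {
    # standardized copy -> correlations are scaled cross products
    z <- scale(v)
    n1 <- nrow(v) - 1L
    retained <- 1L
    for (j in 2:ncol(v)) {
      r <- abs(crossprod(z[, retained, drop = FALSE], z[, j])) / n1
      hit <- which(r >= collinearityThreshold - 1e-12)
      if (length(hit)) {
        log[[colnames(v)[j]]] <-
          paste0("collinear with ", colnames(v)[retained[hit[1L]]])
      } else retained <- c(retained, j)
    }
    v <- v[, retained, drop = FALSE]
  }
  if (ncol(v) < 2L)
    stop("fewer than 2 descriptors survive pruning")
  rl <- if (length(log))
    data.frame(descriptor = names(log), reason = unlist(log, use.names = FALSE),
               stringsAsFactors = FALSE)
  else emptyRemovalLog()
  rownames(rl) <- NULL
  DescriptorMatrix(v, standardized = FALSE, removalLog = rl)
}

#' Standardize descriptor columns to mean 0, sample sd 1
#'
#' Uses full-series statistics, which are stored on the returned object so
#' the same transform can be applied to new cations with
#' \code{\link{applyStandardization}}.
#'
#' @param m a pruned, unstandardized \linkS4class{DescriptorMatrix}.
#' @return a standardized \linkS4class{DescriptorMatrix}.
#' @export
standardizeDescriptors <- function(m) {
  v <- m@values
  if (anyNA(v)) stop("standardize after pruning: NA values present")
  mu <- colMeans(v)
  sdv <- apply(v, 2L, stats::sd)
  zero <- which(sdv == 0)
  if (length(zero))
    stop("zero standard deviation in column '", colnames(v)[zero[1L]],
         "' — pruning was skipped")
  z <- sweep(sweep(v, 2L, mu, "-"), 2L, sdv, "/")
  DescriptorMatrix(z, standardized = TRUE, columnMeans = mu,
                   columnSds = sdv, removalLog = m@removalLog)
}

#' Apply a stored standardization to new descriptor values
#'
#' @param m a standardized \linkS4class{DescriptorMatrix} carrying column
#'   means/sds.
#' @param newValues numeric matrix with (a superset of) m's descriptor
#'   columns.
#' @return numeric matrix of standardized values, columns in m's order.
#' @export
applyStandardization <- function(m, newValues) {
  stopIfNot(isStandardized(m), "m carries no standardization statistics")
  newValues <- asMatrixX(newValues)
  miss <- setdiff(descriptorNames(m), colnames(newValues))
  if (length(miss))
    stop("missing descriptor columns: ", paste(miss, collapse = ", "))
  v <- newValues[, descriptorNames(m), drop = FALSE]
  sweep(sweep(v, 2L, m@columnMeans, "-"), 2L, m@columnSds, "/")
}

#' Deterministic stratified fold assignment
#'
#' Observations are sorted by ascending response (ties broken by input
#' order) and dealt round-robin into folds: the observation of zero-based
#' rank j goes to fold (j mod nFolds) + 1. Every fold therefore contains
#' "every tenth cation" of the sorted series at the default 10 folds, so
#' fold response ranges interleave.
#'
#' @param x a \linkS4class{PropertySeries} or a numeric response vector.
#' @param nFolds number of folds (default 10).
#' @return a \linkS4class{FoldAssignment}.
#' @examples
#' assignFolds(c(5, 1, 3, 2, 4), nFolds = 2)
#' @export
assignFolds <- function(x, nFolds = 10) {
  y <- if (is(x, "PropertySeries")) x@records$logK else as.numeric(x)
  n <- length(y)
  stopIfNot(nFolds >= 2, "need at least 2 folds")
  stopIfNot(nFolds <= n, "more folds (%d) than observations (%d)", nFolds, n)
  ord <- stableOrder(y)
  fold <- integer(n)
  fold[ord] <- (seq_len(n) - 1L) %% as.integer(nFolds) + 1L
  new("FoldAssignment", nFolds = as.integer(nFolds), foldOf = fold)
}

#' Write / read a descriptor matrix as delimited text
#'
#' Round-trips the matrix with row ids in the first column ("id").
#'
#' @param m a \linkS4class{DescriptorMatrix}.
#' @param path file path.
#' @param sep field separator.
#' @return \code{writeDescriptorMatrix}: \code{path} invisibly;
#'   \code{readDescriptorMatrix}: an unstandardized
#'   \linkS4class{DescriptorMatrix}.
#' @export
writeDescriptorMatrix <- function(m, path, sep = ",") {
  df <- data.frame(id = rowIds(m), as.data.frame(m@values),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDescriptorMatrix
#' @export
readDescriptorMatrix <- function(path, sep = ",") {
  stopIfNot(file.exists(path), "file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  stopIfNot(names(df)[1L] == "id", "first column must be 'id'")
  v <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- as.character(df$id)
  DescriptorMatrix(v, standardized = FALSE)
}

#' Read a QsarDB-style archive directory (read-only, plain-text layout)
#'
#' Maps a directory holding \code{compounds.csv} (columns id, smiles),
#' \code{properties.csv} (columns id, value) and \code{descriptors.csv}
#' (id + one column per descriptor) onto a series and descriptor matrix.
#' This is a light import of archive content exported to delimited text,
#' not a parser for the binary/XML archive format.
#'
#' @param dir archive directory.
#' @param solute solute label for the series.
#' @return list with elements \code{series} and \code{descriptors}.
#' @export
readQsardbArchive <- function(dir, solute = basename(dir)) {
  stopIfNot(dir.exists(dir), "archive directory not found: %s", dir)
  comp <- file.path(dir, "compounds.csv")
  prop <- file.path(dir, "properties.csv")
  desc <- file.path(dir, "descriptors.csv")
  for (f in c(comp, prop, desc))
    stopIfNot(file.exists(f), "archive is missing %s", basename(f))
  cdf <- utils::read.csv(comp, stringsAsFactors = FALSE, check.names = FALSE)
  pdf <- utils::read.csv(prop, stringsAsFactors = FALSE, check.names = FALSE)
  idx <- match(cdf$id, pdf$id)
  stopIfNot(!anyNA(idx), "property values missing for some compounds")
  series <- PropertySeries(solute, cdf$id, cdf$smiles,
                           as.numeric(pdf$value[idx]))
  dm <- readDescriptorMatrix(desc)
  stopIfNot(identical(rowIds(dm), cdf$id),
            "descriptor rows do not match compound order")
  list(series = series, descriptors = dm)
}
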