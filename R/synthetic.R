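#' Settings for the planted-signal synthetic data generator
#'
#' Defaults emulate the shape of the study data the pipeline is built
#' for: about 60 cations, a few hundred descriptors after pruning, a
#' sparse interpretable signal of 4 descriptors, and noise calibrated so
#' the population r-squared of the true model is 0.9.
#'
#' @param n observations (default 60).
#' @param p base descriptor count before decoys (default 200).
#' @param kTrue planted signal size (default 4).
#' @param betaTrue planted standardized coefficients (default
#'   c(1, -0.8, 0.6, -0.5)).
#' @param targetR2 population r-squared the noise is calibrated to
#'   (default 0.9).
#' @param nCollinearDecoys columns duplicated from signal columns at
#'   |r| = 0.995 (default 5).
#' @param nConstantDecoys constant columns (default 3).
#' @param nOutliers anomalous rows available to
#'   \code{\link{injectAnomalies}} (default 0).
#' @param rho within-block correlation of the base matrix (default 0.3).
#' @param blockSize columns per correlated block; the default (5, shrunk
#'   when p is small so each planted descriptor gets its own block) suits
#'   the usual p of a few hundred.
#' @param interceptTrue baseline added to y (default 1.2, a mid-range
#'   log K).
#' @param seed mandatory RNG seed.
#' @return a \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(n = 60L, p = 200L, kTrue = 4L,
                          betaTrue = c(1, -0.8, 0.6, -0.5),
                          targetR2 = 0.9, nCollinearDecoys = 5L,
                          nConstantDecoys = 3L, nOutliers = 0L,
                          rho = 0.3, blockSize = NULL, interceptTrue = 1.2,
                          seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  if (is.null(blockSize))
    blockSize <- max(1L, min(5L, as.integer(p) %/% max(1L, as.integer(kTrue))))
  new("SyntheticSpec", n = as.integer(n), p = as.integer(p),
      kTrue = as.integer(kTrue), betaTrue = as.numeric(betaTrue),
      targetR2 = targetR2, nCollinearDecoys = as.integer(nCollinearDecoys),
      nConstantDecoys = as.integer(nConstantDecoys),
      nOutliers = as.integer(nOutliers), rho = rho,
      blockSize = as.integer(blockSize),
      interceptTrue = interceptTrue, seed = as.integer(seed))
}

# shared generator core; nonlinearAmplitude 0 gives the linear generator
generatePlanted <- function(spec, nonlinearAmplitude) {
  n <- spec@n; p <- spec@p; k <- spec@kTrue
  withSeed(spec@seed, {
    # block-correlated base matrix: within a block x = sqrt(rho) u + ...
    nBlocks <- ceiling(p / spec@blockSize)
    common <- matrix(stats::rnorm(n * nBlocks), n, nBlocks)
    X <- matrix(NA_real_, n, p)
    for (j in seq_len(p)) {
      b <- (j - 1L) %/% spec@blockSize + 1L
      X[, j] <- sqrt(spec@rho) * common[, b] +
        sqrt(1 - spec@rho) * stats::rnorm(n)
    }
    colnames(X) <- sprintf("D%03d", seq_len(p))
    rownames(X) <- sprintf("cation%03d", seq_len(n))
    # signal = first column of the first kTrue blocks (distinct blocks)
    signalIdx <- (seq_len(k) - 1L) * spec@blockSize + 1L
    signalNames <- colnames(X)[signalIdx]
    linear <- drop(X[, signalIdx, drop = FALSE] %*% spec@betaTrue)
    # population variances: signal columns are standard normal and live in
    # distinct blocks, so var(linear) = sum(beta^2); the smooth term
    # x1 x2 + 0.5 (x1^2 - 1) has variance 1.5 and zero covariance with the
    # linear part (odd/even moment orthogonality)
    varLinear <- sum(spec@betaTrue^2)
    nl <- 0
    varNl <- 0
    if (nonlinearAmplitude != 0) {
      x1 <- X[, signalIdx[1L]]; x2 <- X[, signalIdx[2L]]
      nl <- nonlinearAmplitude * (x1 * x2 + 0.5 * (x1^2 - 1))
      varNl <- nonlinearAmplitude^2 * 1.5
    }
    varSignal <- varLinear + varNl
    noiseSd <- sqrt(varSignal * (1 - spec@targetR2) / spec@targetR2)
    yClean <- spec@interceptTrue + linear + nl
    y <- yClean + stats::rnorm(n, sd = noiseSd)
    names(y) <- rownames(X)
    # collinear decoys: exact sample correlation 0.995 with a signal column
    cd <- matrix(NA_real_, n, spec@nCollinearDecoys)
    if (spec@nCollinearDecoys > 0L) {
      for (d in seq_len(spec@nCollinearDecoys)) {
        s <- X[, signalIdx[(d - 1L) %% k + 1L]]
        z <- stats::rnorm(n)
        sStd <- (s - mean(s)) / stats::sd(s)
        zr <- stats::residuals(stats::lm(z ~ s))
        zStd <- zr / stats::sd(zr)
        cd[, d] <- 0.995 * sStd + sqrt(1 - 0.995^2) * zStd
      }
      colnames(cd) <- sprintf("CD%02d", seq_len(spec@nCollinearDecoys))
    }
    cc <- matrix(1, n, spec@nConstantDecoys)
    if (spec@nConstantDecoys > 0L)
      colnames(cc) <- sprintf("CC%02d", seq_len(spec@nConstantDecoys))
    full <- cbind(X,
                  if (spec@nCollinearDecoys > 0L) cd,
                  if (spec@nConstantDecoys > 0L) cc)
    rownames(full) <- rownames(X)
  })
  list(X = DescriptorMatrix(full, standardized = FALSE),
       y = y,
       truth = list(signal = signalNames, signalIndices = signalIdx,
                    beta = spec@betaTrue, noiseSd = noiseSd,
                    intercept = spec@interceptTrue, yClean = yClean,
                    nonlinearAmplitude = nonlinearAmplitude))
}

#' Generate a planted sparse linear dataset
#'
#' Draws a block-correlated descriptor matrix (standard normal marginals,
#' within-block correlation \code{rho}), plants a sparse linear signal on
#' one column of each of the first kTrue blocks, and adds Gaussian noise
#' whose variance is computed in closed form so the population r-squared
#' of the true model equals \code{targetR2}. Collinear decoys (exact
#' sample correlation 0.995 with signal columns) and constant decoys are
#' appended for the pruning stage to find.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return list(X = unstandardized \linkS4class{DescriptorMatrix},
#'   y = named response vector, truth = record of signal names/indices,
#'   coefficients, noise sd and the noise-free response).
#' @examples
#' d <- makePlantedLinear(syntheticSpec(n = 30, p = 20, seed = 7))
#' d$truth$signal
#' @export
makePlantedLinear <- function(spec) generatePlanted(spec, 0)

#' Generate a planted dataset with a smooth nonlinear component
#'
#' As \code{\link{makePlantedLinear}} plus
#' amplitude * (x1 x2 + 0.5 (x1^2 - 1)) on the first two signal
#' descriptors; the noise calibration accounts for the extra (orthogonal)
#' signal variance. Amplitude 0 reproduces the linear generator exactly.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param amplitude scale of the nonlinear term (default 1).
#' @return as \code{\link{makePlantedLinear}}.
#' @export
makePlantedNonlinear <- function(spec, amplitude = 1) {
  stopIfNot(spec@kTrue >= 2L, "nonlinear generator needs kTrue >= 2")
  generatePlanted(spec, amplitude)
}

#' Inject high-leverage and high-residual observations
#'
#' Appends anomalous rows to a planted dataset: leverage rows place the
#' signal descriptors at 4 standard deviations (response consistent with
#' the true model), residual rows copy a typical descriptor profile but
#' shift the response by 5 noise standard deviations.
#'
#' @param X \linkS4class{DescriptorMatrix} or matrix from the generator.
#' @param y response vector.
#' @param truth the generator's truth record.
#' @param nLeverage,nResidual how many rows of each kind (defaults 1).
#' @param seed RNG seed.
#' @return list(X, y, leverageIndices, residualIndices).
#' @export
injectAnomalies <- function(X, y, truth, nLeverage = 1L, nResidual = 1L,
                            seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  dm <- if (is(X, "DescriptorMatrix")) X@values else asMatrixX(X)
  n <- nrow(dm)
  total <- nLeverage + nResidual
  if (total == 0L)
    return(list(X = X, y = y, leverageIndices = integer(0),
                residualIndices = integer(0)))
  stopIfNot(total < n / 10, "too many anomalies for n = %d", n)
  withSeed(seed, {
    newRows <- matrix(stats::rnorm(total * ncol(dm), sd = 0.3), total,
                      ncol(dm), dimnames = list(NULL, colnames(dm)))
    si <- truth$signalIndices
    newY <- numeric(total)
    for (i in seq_len(nLeverage)) {
      newRows[i, si] <- 4 * c(1, -1)[(i - 1L) %% 2L + 1L]
      newY[i] <- truth$intercept +
        sum(truth$beta * newRows[i, si]) +
        stats::rnorm(1L, sd = truth$noiseSd)
    }
    for (i in seq_len(nResidual)) {
      j <- nLeverage + i
      donor <- sample.int(n, 1L)
      newRows[j, ] <- dm[donor, ]
      newY[j] <- truth$intercept + sum(truth$beta * newRows[j, si]) +
        5 * truth$noiseSd * c(1, -1)[(i - 1L) %% 2L + 1L]
    }
  })
  rownames(newRows) <- sprintf("anomaly%02d", seq_len(total))
  out <- rbind(dm, newRows)
  yOut <- c(y, stats::setNames(newY, rownames(newRows)))
  list(X = DescriptorMatrix(out, standardized = FALSE), y = yOut,
       leverageIndices = n + seq_len(nLeverage),
       residualIndices = n + nLeverage + seq_len(nResidual))
}

#' Write a synthetic dataset to a directory
#'
#' Emits the same delimited-text formats the readers consume: a series
#' CSV (placeholder SMILES), a descriptor-matrix CSV and a truth JSON.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param dir output directory (created if needed).
#' @return list of written paths, invisibly.
#' @export
writeSyntheticDataset <- function(spec, dir) {
  d <- makePlantedLinear(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seriesPath <- file.path(dir, "series.csv")
  series <- PropertySeries("synthetic", names(d$y),
                           rep("C", length(d$y)), unname(d$y))
  writeSeries(series, seriesPath)
  descPath <- file.path(dir, "descriptors.csv")
  writeDescriptorMatrix(d$X, descPath)
  truthPath <- file.path(dir, "truth.json")
  jsonlite::write_json(d$truth[c("signal", "beta", "noiseSd", "intercept")],
                       truthPath, auto_unbox = TRUE, digits = NA)
  invisible(list(series = seriesPath, descriptors = descPath,
                 truth = truthPath))
}
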