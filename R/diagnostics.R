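#' Leverage values and the critical leverage
#'
#' Diagonal of the hat matrix H = X (X'X)^{-1} X' for the design made of
#' the model's descriptor columns plus a constant column, together with
#' the high-leverage threshold h*3 = 3 (k+1) / n.
#'
#' @param X numeric matrix of the model's descriptor columns (no constant
#'   column; it is appended internally).
#' @return list(h, hCrit3, k, n).
#' @export
leverageValues <- function(X) {
  X <- asMatrixX(X)
  n <- nrow(X); k <- ncol(X)
  D <- cbind(1, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) stop("rank-deficient design")
  Q <- qr.Q(qrD)
  h <- rowSums(Q^2)
  list(h = h, hCrit3 = 3 * (k + 1) / n, k = k, n = n)
}

#' Internally studentized residuals of a linear model
#'
#' e_i = y_i - yhat_i, sigma^2 = e'e / (n - k - 1), and
#' r_i = (yhat_i - y_i) / (sigma sqrt(1 - h_ii)); the sign convention
#' makes positive r_i an overprediction. Observations with h_ii
#' numerically 1 get NA and are flagged undefined downstream.
#'
#' @param model a \linkS4class{LinearModel} fitted on (X, y).
#' @param X matrix with the model's descriptor columns.
#' @param y response vector.
#' @return list(r, e, sigma2, h, hCrit3, k, n).
#' @export
standardizedResiduals <- function(model, X, y) {
  if (is(X, "DescriptorMatrix")) X <- X@values
  X <- asMatrixX(X)
  Xm <- X[, descriptorNames(model), drop = FALSE]
  lev <- leverageValues(Xm)
  n <- lev$n; k <- lev$k
  stopIfNot(n > k + 1L, "need n > k + 1")
  yhat <- predict(model, X)
  e <- y - yhat
  sigma2 <- sum(e^2) / (n - k - 1)
  if (sqrt(sigma2) <= 1e-10 * max(1, stats::sd(y))) {
    # numerically perfect fit: the standardized residuals are all zero
    r <- rep(0, n)
  } else {
    denom <- sqrt(sigma2) * sqrt(pmax(1 - lev$h, 0))
    r <- ifelse(lev$h > 1 - 1e-10, NA_real_, (yhat - y) / denom)
  }
  c(list(r = r, e = e, sigma2 = sigma2), lev)
}

#' Cook's distance from leverage and standardized residuals
#'
#' D_i = r_i^2 / (k + 1) * h_ii / (1 - h_ii). NA standardized residuals
#' (undefined at h_ii = 1) propagate.
#'
#' @param h leverage vector.
#' @param r standardized residual vector.
#' @param k number of descriptors in the model.
#' @return numeric vector of distances.
#' @export
cooksDistance <- function(h, r, k) {
  stopIfNot(length(h) == length(r), "h and r lengths differ")
  r^2 / (k + 1) * h / (1 - h)
}

#' Influence table for a fitted linear model
#'
#' Combines leverage, internally studentized residuals and Cook's
#' distance with the conventional flags: high leverage above
#' h*3 = 3(k+1)/n, moderate leverage above \code{moderateFactor}(k+1)/n
#' (default 2), moderate residual |r| > 2, high residual |r| > 3,
#' influential D > 1.
#'
#' @param model a \linkS4class{LinearModel} fitted on (X, y).
#' @param X matrix (or \linkS4class{DescriptorMatrix}) with the model's
#'   descriptor columns; rownames are used as observation ids.
#' @param y response vector.
#' @param moderateFactor multiplier of (k+1)/n for the moderate-leverage
#'   threshold (default 2).
#' @return an \linkS4class{InfluenceTable}.
#' @export
influenceTable <- function(model, X, y, moderateFactor = 2) {
  if (is(X, "DescriptorMatrix")) X <- X@values
  X <- asMatrixX(X)
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("obs%03d", seq_len(nrow(X)))
  sr <- standardizedResiduals(model, X, y)
  D <- cooksDistance(sr$h, sr$r, sr$k)
  hCrit2 <- moderateFactor * (sr$k + 1) / sr$n
  undef <- is.na(sr$r)
  tab <- data.frame(
    id = ids, leverage = sr$h, residual = sr$e, stdResidual = sr$r,
    cooksD = D,
    moderateLeverage = sr$h > hCrit2,
    highLeverage = sr$h > sr$hCrit3,
    moderateResidual = !undef & abs(sr$r) > 2,
    highResidual = !undef & abs(sr$r) > 3,
    influential = !undef & !is.na(D) & D > 1,
    undefined = undef,
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  new("InfluenceTable", table = tab, sigma2 = sr$sigma2,
      hCrit3 = sr$hCrit3, hCrit2 = hCrit2, k = as.integer(sr$k),
      n = as.integer(sr$n))
}

#' Structured influence report
#'
#' Lists observation ids per flag category (moderate categories exclude
#' the corresponding high category) and emits the influence-plot scatter
#' data: leverage vs standardized residual with point size proportional
#' to Cook's distance.
#'
#' @param table an \linkS4class{InfluenceTable}.
#' @return list(categories, thresholds, scatter).
#' @export
influenceReport <- function(table) {
  t <- table@table
  list(
    categories = list(
      highLeverage = t$id[t$highLeverage],
      moderateLeverage = t$id[t$moderateLeverage & !t$highLeverage],
      highResidual = t$id[t$highResidual],
      moderateResidual = t$id[t$moderateResidual & !t$highResidual],
      influential = t$id[t$influential],
      undefined = t$id[t$undefined]),
    thresholds = list(hCrit3 = table@hCrit3, hCrit2 = table@hCrit2,
                      moderateResidual = 2, highResidual = 3,
                      influential = 1),
    scatter = t[, c("id", "leverage", "stdResidual", "cooksD")])
}

#' Write influence-plot data as CSV
#'
#' @param table an \linkS4class{InfluenceTable}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeInfluenceCsv <- function(table, path) {
  utils::write.csv(influenceReport(table)$scatter, path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
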