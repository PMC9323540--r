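#' Greedy forward selection with single-swap substitution passes
#'
#' Builds a descriptor set of size k for a kernel model (or any scorer):
#' each forward step adds the pool descriptor maximizing the score; after
#' every addition, substitution passes scan the selected positions, try
#' every pool replacement, and adopt the single best strictly-improving
#' swap, repeating until no swap improves; then the next forward step
#' runs, until the set reaches size k. Scores are memoized, so the
#' scorer must be deterministic in the descriptor set.
#'
#' @param scoreFun function(character vector of descriptors) -> numeric
#'   score to maximize (typically cross-validated test r-squared).
#' @param pool candidate descriptor names.
#' @param k target set size.
#' @return list with the \code{selected} set (character), its
#'   \code{score}, and \code{history} (data.frame of size, score and the
#'   concluded set at each size).
#' @export
greedySubstitutionSelect <- function(scoreFun, pool, k) {
  stopIfNot(length(pool) >= k, "pool (%d) smaller than k (%d)",
            length(pool), k)
  cache <- new.env(parent = emptyenv())
  score <- function(set) {
    key <- paste(sort(set), collapse = "\r")
    if (is.null(cache[[key]])) cache[[key]] <- scoreFun(set)
    cache[[key]]
  }
  selected <- character(0)
  history <- list()
  for (size in seq_len(k)) {
    candidates <- setdiff(pool, selected)
    s <- vapply(candidates, function(d) score(c(selected, d)), numeric(1))
    selected <- c(selected, candidates[which.max(s)])
    # substitution passes: one best strictly-improving swap per pass
    repeat {
      cur <- score(selected)
      bestGain <- 0; bestSet <- NULL
      for (pos in seq_along(selected)) {
        for (repl in setdiff(pool, selected)) {
          trial <- selected
          trial[pos] <- repl
          gain <- score(trial) - cur
          if (gain > bestGain + 1e-15) {
            bestGain <- gain
            bestSet <- trial
          }
        }
      }
      if (is.null(bestSet)) break
      selected <- bestSet
    }
    history[[size]] <- data.frame(size = size, score = score(selected),
                                  set = paste(selected, collapse = "+"),
                                  stringsAsFactors = FALSE)
  }
  list(selected = selected, score = score(selected),
       history = do.call(rbind, history))
}

#' Kernel-model descriptor selection with the 20 percent size rule
#'
#' Runs \code{\link{greedySubstitutionSelect}} with a cross-validated
#' scorer for the requested kernel method, then applies the
#' error-improvement rule over the concluded set at each size: a larger
#' set is kept only while it corrects at least
#' \code{improvementFraction} of the previous error (1 - cv r-squared).
#' During selection the hyperparameters are held at defaults (SVR: C = 1,
#' epsilon = 0.001, gamma = "auto"); grid tuning belongs to
#' \code{\link{tuneSvr}} on the concluded set.
#'
#' @param method "svr" or "gpr".
#' @param X standardized descriptor matrix.
#' @param y response vector.
#' @param folds a \linkS4class{FoldAssignment}.
#' @param kMax largest set size examined (default 6).
#' @param improvementFraction size-rule fraction (default 0.20).
#' @param pool candidate descriptors (default: all columns of X).
#' @param ... passed to the method's spec constructor (e.g. GPR restarts).
#' @return list(selected, k, cvR2, history).
#' @export
selectKernelModel <- function(method = c("svr", "gpr"), X, y, folds,
                              kMax = 6L, improvementFraction = 0.20,
                              pool = NULL, ...) {
  method <- match.arg(method)
  if (is(X, "DescriptorMatrix")) X <- X@values
  X <- asMatrixX(X)
  if (is.null(pool)) pool <- colnames(X)
  specFor <- function(set) switch(method,
    svr = svrSpec(descriptors = set, ...),
    gpr = gprSpec(descriptors = set, ...))
  scorer <- function(set) cvTestR2(specFor(set), X, y, folds)
  gs <- greedySubstitutionSelect(scorer, pool, min(kMax, length(pool)))
  errs <- 1 - gs$history$score
  k <- 1L
  while (k < nrow(gs$history)) {
    if (errs[k] <= 0) break
    if ((errs[k] - errs[k + 1L]) / errs[k] >= improvementFraction - 1e-12)
      k <- k + 1L
    else break
  }
  selected <- strsplit(gs$history$set[k], "+", fixed = TRUE)[[1L]]
  list(selected = selected, k = k, cvR2 = gs$history$score[k],
       history = gs$history)
}
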