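#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded internals do not
#' perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# single place for the Pearson correlation used by all selection routines
pearson <- function(x, y) stats::cor(x, y, method = "pearson")

# stable ascending order with ties broken by input position
stableOrder <- function(x) order(x, seq_along(x))

# deterministic 31-bit seed from a base seed and a column name
columnSeed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

stopIfNot <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

asMatrixX <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) stop("'X' must be a numeric matrix")
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  X
}
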