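#' Assemble and validate a pipeline configuration
#'
#' @param seriesPath CSV/TSV with id, smiles, logK columns (or NULL when
#'   \code{synthetic} is given).
#' @param descriptorPath CSV/TSV descriptor matrix (id first column), or
#'   NULL when \code{synthetic} is given.
#' @param synthetic optional \linkS4class{SyntheticSpec}; replaces the two
#'   input paths.
#' @param method one of "mlr", "svr", "gpr".
#' @param nFolds folds for cross-validation (default 10).
#' @param collinearityThreshold pruning threshold (default 0.95).
#' @param corrThreshold expulsion threshold (default 0.4, MLR only).
#' @param improvementFraction model-size rule (default 0.20).
#' @param kMax largest model size (default 5).
#' @param svrGrid \linkS4class{HyperparamGrid} for tuning (NULL skips
#'   tuning; default \code{\link{defaultSvrGrid}()} when method = "svr").
#' @param gprRestarts marginal-likelihood restarts (default 5).
#' @param permutationRepeats permutation-importance repeats (default 30).
#' @param seed top-level seed; per-stage seeds are derived by fixed
#'   offsets.
#' @param outputDir directory for artifacts.
#' @return validated config (list).
#' @export
pipelineConfig <- function(seriesPath = NULL, descriptorPath = NULL,
                           synthetic = NULL,
                           method = c("mlr", "svr", "gpr"), nFolds = 10L,
                           collinearityThreshold = 0.95,
                           corrThreshold = 0.4,
                           improvementFraction = 0.20, kMax = 5L,
                           svrGrid = NULL, gprRestarts = 5L,
                           permutationRepeats = 30L, seed,
                           outputDir = tempfile("ilqspr_run_")) {
  method <- match.arg(method)
  if (missing(seed)) stop("'seed' is mandatory")
  if (is.null(synthetic))
    stopIfNot(!is.null(seriesPath) && !is.null(descriptorPath),
              "give seriesPath + descriptorPath, or a synthetic spec")
  stopIfNot(collinearityThreshold > 0 && collinearityThreshold <= 1,
            "collinearityThreshold out of (0, 1]")
  stopIfNot(corrThreshold >= 0 && corrThreshold <= 1,
            "corrThreshold out of [0, 1]")
  stopIfNot(improvementFraction > 0 && improvementFraction < 1,
            "improvementFraction out of (0, 1)")
  if (method == "svr" && is.null(svrGrid)) svrGrid <- defaultSvrGrid()
  list(seriesPath = seriesPath, descriptorPath = descriptorPath,
       synthetic = synthetic, method = method, nFolds = as.integer(nFolds),
       collinearityThreshold = collinearityThreshold,
       corrThreshold = corrThreshold,
       improvementFraction = improvementFraction, kMax = as.integer(kMax),
       svrGrid = svrGrid, gprRestarts = as.integer(gprRestarts),
       permutationRepeats = as.integer(permutationRepeats),
       seed = as.integer(seed), outputDir = outputDir)
}

configHash <- function(config) {
  keep <- config[setdiff(names(config), "outputDir")]
  if (!is.null(keep$svrGrid))
    keep$svrGrid <- list(C = keep$svrGrid@CValues,
                         epsilon = keep$svrGrid@epsilonValues,
                         gamma = keep$svrGrid@gammaValues)
  if (!is.null(keep$synthetic)) {
    s <- keep$synthetic
    keep$synthetic <- lapply(stats::setNames(slotNames(s), slotNames(s)),
                             function(nm) slot(s, nm))
  }
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(keep, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

pipelineLog <- function(con, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                 sprintf(fmt, ...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full QSPR workflow
#'
#' Stages, in workflow order: load (or simulate) the series and
#' descriptor matrix; prune and standardize descriptors; assign
#' deterministic sorted folds; select descriptors (expulsion search for
#' MLR, greedy substitution for SVR/GPR, both under the 20 percent size
#' rule); tune SVR hyperparameters on the concluded set; cross-validate;
#' compute permutation importances; run influence diagnostics (linear
#' models only); and write all artifacts, stamped with the config hash
#' and seed. Reruns with an identical config reproduce identical JSON
#' artifacts.
#'
#' @param config from \code{\link{pipelineConfig}}.
#' @return invisibly, a list with the fitted model, fold statistics,
#'   importances, influence table (or NULL) and artifact paths.
#' @export
runPipeline <- function(config) {
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(config$outputDir, "run.log")
  logCon <- file(logPath, open = "wt")
  on.exit(close(logCon))
  hash <- configHash(config)
  stamp <- list(configHash = hash, seed = config$seed)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  pipelineLog(logCon, "run start (config %s, seed %d, method %s)", hash,
              config$seed, config$method)

  if (!is.null(config$synthetic)) {
    d <- step("simulate", makePlantedLinear(config$synthetic))
    raw <- d$X
    y <- unname(d$y)
    ids <- rownames(d$X@values)
  } else {
    series <- step("read_series", readSeries(config$seriesPath))
    raw <- step("read_descriptors",
                readDescriptorMatrix(config$descriptorPath))
    stopIfNot(identical(rowIds(raw), cationIds(series)),
              "descriptor rows do not match series order")
    y <- unname(logK(series))
    ids <- cationIds(series)
  }
  pipelineLog(logCon, "loaded %d observations x %d descriptors",
              nrow(raw@values), ncol(raw@values))

  pruned <- step("prune",
                 pruneDescriptors(raw, config$collinearityThreshold))
  dm <- step("standardize", standardizeDescriptors(pruned))
  pipelineLog(logCon, "pruned to %d descriptors (%d removed)",
              ncol(dm@values), nrow(removalLog(dm)))
  folds <- step("folds", assignFolds(y, config$nFolds))
  X <- dm@values

  tuned <- NULL
  if (config$method == "mlr") {
    sel <- step("select", selectMlr(X, y, folds, kMax = config$kMax,
                                    corrThreshold = config$corrThreshold,
                                    improvementFraction =
                                      config$improvementFraction))
    model <- sel$model
    spec <- mlrSpec(descriptorNames(model))
  } else {
    sel <- step("select", selectKernelModel(
      config$method, X, y, folds, kMax = config$kMax,
      improvementFraction = config$improvementFraction))
    if (config$method == "svr") {
      tuned <- if (!is.null(config$svrGrid))
        step("tune", tuneSvr(X[, sel$selected, drop = FALSE], y, folds,
                             config$svrGrid))
      else list(C = 1, epsilon = 0.001, gamma = "auto")
      spec <- svrSpec(sel$selected, C = tuned$C, epsilon = tuned$epsilon,
                      gamma = tuned$gamma)
      model <- step("fit", spec$fit(X, y))
    } else {
      spec <- gprSpec(sel$selected, restarts = config$gprRestarts,
                      seed = config$seed + 3L)
      model <- step("fit", spec$fit(X, y))
    }
  }
  pipelineLog(logCon, "selected %d descriptors: %s",
              length(descriptorNames(model)),
              paste(descriptorNames(model), collapse = ", "))

  stats <- step("evaluate", crossValidate(spec, X, y, folds))
  imp <- step("importance", permutationImportance(
    model, X[, descriptorNames(model), drop = FALSE], y,
    nRepeats = config$permutationRepeats, seed = config$seed + 2L))
  infl <- NULL
  if (config$method == "mlr")
    infl <- step("diagnose", influenceTable(model, X, y))

  paths <- writeArtifacts(config$outputDir, stamp, model, dm, stats, imp,
                          infl, ids, y, spec, X)
  pipelineLog(logCon, "run complete; artifacts in %s", config$outputDir)
  invisible(list(model = model, stats = stats, importance = imp,
                 influence = infl, selection = sel, tuned = tuned,
                 folds = folds, descriptors = dm, y = y, paths = paths))
}

writeArtifacts <- function(dir, stamp, model, dm, stats, imp, infl, ids,
                           y, spec, X) {
  paths <- list()
  paths$model <- file.path(dir, "model.json")
  exportModelJson(model, paths$model, descriptorMatrix = dm,
                  provenance = stamp)
  paths$foldStats <- file.path(dir, "fold_stats.json")
  jsonlite::write_json(c(stamp, list(
    perFold = stats@perFold,
    aggregate = lapply(stats@aggregate, as.list),
    pooled = as.list(stats@pooled))),
    paths$foldStats, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$importance <- file.path(dir, "importance.json")
  jsonlite::write_json(c(stamp, list(
    nRepeats = imp@nRepeats, table = imp@table)),
    paths$importance, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # predicted-vs-experimental scatter data for plotting
  paths$scatter <- file.path(dir, "predicted_vs_experimental.csv")
  utils::write.csv(data.frame(id = ids, experimental = y,
                              predicted = spec$predict(model, X)),
                   paths$scatter, row.names = FALSE, quote = FALSE)
  if (!is.null(infl)) {
    paths$influence <- file.path(dir, "influence.csv")
    writeInfluenceCsv(infl, paths$influence)
    paths$influenceReport <- file.path(dir, "influence_report.json")
    rep <- influenceReport(infl)
    jsonlite::write_json(c(stamp, rep[c("categories", "thresholds")]),
                         paths$influenceReport, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  paths
}
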