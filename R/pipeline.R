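# Orchestration: configuration, tree-table I/O, plot summaries, and the
# cloud-to-report pipeline.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis chain with its
#' conventional default: 80 % random thinning, SOR with k = 10 / 2 sigma,
#' 0.5 m ground grid, the 1.25-1.35 m breast-height slice, 4 neighbours,
#' a 2.5 m edge buffer, the 72 deg standard angle, 5 m quadrats and
#' 10 cm diameter classes from 5 cm. Serializable to YAML with
#' [saveConfig()] / [loadConfig()].
#'
#' @param plotSize plot side (m).
#' @param retainFraction random-thinning retention.
#' @param sorK,sorNSigma statistical outlier removal parameters.
#' @param groundCell,groundTol ground-classifier grid cell (m) and height
#'   tolerance (m).
#' @param sliceLow,sliceHigh DBH slice bounds (m).
#' @param bandLow,bandHigh trunk-detection band (m).
#' @param clusterRadius,minCluster trunk clustering parameters.
#' @param k neighbours per structure unit.
#' @param buffer edge-buffer width (m).
#' @param alpha0 standard angle (deg).
#' @param quadratSize quadrat side (m) for relative frequency.
#' @param classWidth,classOrigin diameter-class width and origin (cm).
#' @param matchDist stem-matching cap (m) for evaluation.
#' @param seed integer seed for every stochastic stage.
#' @param stages character vector of stages to run, a subset of
#'   `c("preprocess", "extract", "spatial", "nonspatial", "evaluate")`.
#' @param outDir output directory (NULL: no files written).
#' @return an object of class `pipelineConfig`.
#' @export
pipelineConfig <- function(plotSize = 25, retainFraction = 0.8, sorK = 10,
                           sorNSigma = 2, groundCell = 0.5, groundTol = 0.2,
                           sliceLow = 1.25, sliceHigh = 1.35, bandLow = 1.0,
                           bandHigh = 2.0, clusterRadius = 0.3,
                           minCluster = 15, k = 4, buffer = 2.5, alpha0 = 72,
                           quadratSize = 5, classWidth = 10, classOrigin = 5,
                           matchDist = 1, seed = 1,
                           stages = c("preprocess", "extract", "spatial",
                                      "nonspatial", "evaluate"),
                           outDir = NULL) {
  cfg <- list(plotSize = plotSize, retainFraction = retainFraction,
              sorK = sorK, sorNSigma = sorNSigma, groundCell = groundCell,
              groundTol = groundTol, sliceLow = sliceLow,
              sliceHigh = sliceHigh, bandLow = bandLow, bandHigh = bandHigh,
              clusterRadius = clusterRadius, minCluster = minCluster,
              k = k, buffer = buffer, alpha0 = alpha0,
              quadratSize = quadratSize, classWidth = classWidth,
              classOrigin = classOrigin, matchDist = matchDist, seed = seed,
              stages = stages, outDir = outDir)
  stopifnot(retainFraction > 0, retainFraction <= 1, sorK >= 1,
            sliceHigh > sliceLow, buffer < plotSize / 2, k >= 1,
            alpha0 > 0, alpha0 < 360, quadratSize > 0, classWidth > 0)
  bad <- setdiff(stages, c("preprocess", "extract", "spatial", "nonspatial",
                           "evaluate"))
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "pipelineConfig")
}

#' Save / load a pipeline configuration as YAML
#'
#' `loadConfig(saveConfig(cfg, path))` reproduces the configuration
#' exactly.
#'
#' @param config a [pipelineConfig()].
#' @param path YAML file path.
#' @return `saveConfig` the path, invisibly; `loadConfig` the
#'   configuration.
#' @export
saveConfig <- function(config, path) {
  stopifnot(inherits(config, "pipelineConfig"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname saveConfig
#' @export
loadConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (length(raw$outDir) == 0) raw$outDir <- NULL
  do.call(pipelineConfig, raw)
}

#' Write / read a tree table as CSV
#'
#' Column layout: `tree_id`, `species`, `x_m`, `y_m`, `dbh_cm`,
#' `height_m` (plus `source` when present).
#'
#' @param stand a [ForestStand-class].
#' @param path CSV path.
#' @return `writeStandTable` the path invisibly; `readStandTable` a
#'   [ForestStand-class].
#' @export
writeStandTable <- function(stand, path) {
  stopifnot(is(stand, "ForestStand"))
  tr <- treeData(stand)
  out <- data.frame(tree_id = tr$tree_id, species = tr$species,
                    x_m = tr$x, y_m = tr$y, dbh_cm = tr$dbh,
                    height_m = tr$height, stringsAsFactors = FALSE)
  if (!is.null(tr$source)) out$source <- tr$source
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeStandTable
#' @param plotSize plot side (m) of the stand being read.
#' @export
readStandTable <- function(path, plotSize = 25) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  tr <- data.frame(tree_id = d$tree_id, species = d$species,
                   x = d$x_m, y = d$y_m, dbh = d$dbh_cm,
                   height = d$height_m, stringsAsFactors = FALSE)
  if (!is.null(d$source)) tr$source <- d$source
  ForestStand(tr, plotSize)
}

#' Basic plot summary
#'
#' The standard sample-plot descriptors: tree count, mean/max/min DBH and
#' height.
#'
#' @param stand a non-empty [ForestStand-class].
#' @return one-row data.frame: `n`, `meanDBH`, `meanTH`, `maxDBH`,
#'   `minDBH`, `maxTH`, `minTH`.
#' @export
summarizePlot <- function(stand) {
  stopifnot(is(stand, "ForestStand"))
  tr <- treeData(stand)
  if (nrow(tr) == 0) stop("empty stand")
  data.frame(n = nrow(tr),
             meanDBH = mean(tr$dbh), meanTH = mean(tr$height),
             maxDBH = max(tr$dbh), minDBH = min(tr$dbh),
             maxTH = max(tr$height), minTH = min(tr$height))
}

#' Run the full analysis pipeline on a stand (and optionally its cloud)
#'
#' Executes, as requested by `config$stages`: point-cloud preprocessing
#' (thinning, outlier removal, ground classification, TIN DEM, height
#' normalization), individual-tree extraction, spatial structure indices,
#' non-spatial structure, and accuracy evaluation of the extracted against
#' the field table (matched by stem position). Stage failures propagate
#' with the stage name. When `config$outDir` is set, every table is written
#' as CSV along with a JSON run manifest of all parameters used.
#'
#' @param stand a [ForestStand-class] (the field tree table).
#' @param cloud optional [PointCloud-class] of the plot (required for the
#'   preprocess/extract/evaluate stages).
#' @param config a [pipelineConfig()].
#' @param taxonomy optional taxonomy data.frame for the composition
#'   summary.
#' @return named list of stage outputs: `summary`, and depending on
#'   stages, `cloud`, `blsTable`, `spatial`, `spatialSummary`,
#'   `competition`, `diversity`, `importance`, `diameterClasses`,
#'   `composition`, `evaluation`.
#' @export
runPipeline <- function(stand, cloud = NULL, config = pipelineConfig(),
                        taxonomy = NULL) {
  stopifnot(is(stand, "ForestStand"), inherits(config, "pipelineConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  res <- list(summary = summarizePlot(stand))
  norm <- NULL
  if ("preprocess" %in% config$stages && !is.null(cloud)) {
    norm <- stage("preprocess", {
      pc <- randomSample(cloud, config$retainFraction, seed = config$seed)
      pc <- sorDenoise(pc, config$sorK, config$sorNSigma)
      pc <- classifyGround(pc, config$groundCell, config$groundTol)
      dem <- buildDEM(groundPoints(pc))
      normalizeHeights(pc, dem)
    })
    res$cloud <- norm
  }
  if ("extract" %in% config$stages && !is.null(norm)) {
    res$blsTable <- stage("extract", {
      nong <- .subsetCloud(norm,
                           which(pointData(norm)$classification != 2L))
      trees <- segmentTrees(nong, c(config$bandLow, config$bandHigh),
                            config$clusterRadius, config$minCluster)
      extractTreeParameters(trees, sliceLow = config$sliceLow,
                            sliceHigh = config$sliceHigh)
    })
  }
  if ("spatial" %in% config$stages) {
    res$spatial <- stage("spatial",
      spatialIndices(stand, config$k, config$buffer, config$alpha0))
    res$spatialSummary <- plotStructureSummary(res$spatial)
    dom <- abundanceProfile(stand)$species[1]
    res$competition <- stage("spatial",
      classCompetition(res$spatial, species = dom,
                       width = config$classWidth,
                       origin = config$classOrigin))
  }
  if ("nonspatial" %in% config$stages) {
    res$diversity <- stage("nonspatial", diversitySummary(stand))
    res$importance <- stage("nonspatial",
      importanceValueTable(stand, config$quadratSize))
    res$diameterClasses <- stage("nonspatial",
      diameterClasses(stand, config$classWidth, config$classOrigin))
    res$composition <- stage("nonspatial",
      suppressWarnings(compositionSummary(stand, taxonomy)))
  }
  if ("evaluate" %in% config$stages && !is.null(res$blsTable)) {
    res$evaluation <- stage("evaluate", {
      pairs <- matchStems(treeData(stand), res$blsTable,
                          maxDist = config$matchDist)
      evaluatePairs(pairs)
    })
  }
  if (!is.null(config$outDir)) .writeReports(res, stand, config)
  invisible(res)
}

.writeReports <- function(res, stand, config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$outDir, f)
  writeStandTable(stand, p("stand.csv"))
  utils::write.csv(res$summary, p("plot_summary.csv"), row.names = FALSE)
  if (!is.null(res$spatial)) {
    utils::write.csv(res$spatial, p("spatial_indices.csv"),
                     row.names = FALSE)
    utils::write.csv(res$competition$byClass, p("class_competition.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$diversity)) {
    utils::write.csv(res$diversity, p("diversity.csv"), row.names = FALSE)
    utils::write.csv(res$importance, p("importance_values.csv"),
                     row.names = FALSE)
    dc <- res$diameterClasses
    utils::write.csv(data.frame(class = names(dc$counts),
                                count = as.integer(dc$counts)),
                     p("diameter_classes.csv"), row.names = FALSE)
  }
  if (!is.null(res$blsTable))
    utils::write.csv(res$blsTable, p("bls_trees.csv"), row.names = FALSE)
  if (!is.null(res$evaluation))
    utils::write.csv(res$evaluation, p("evaluation.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(config), p("run_manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(NULL)
}
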