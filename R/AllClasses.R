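#' @import methods
NULL

#' PointCloud: a set of 3-D points with optional per-point attributes
#'
#' Coordinates are metres in a local (plot-relative) frame. Per-point
#' attributes live in `pointData` (one row per point); typical columns are
#' `classification` (LAS convention: 2 = ground, 1 = unclassified) and
#' `treeId`. Free-form provenance (e.g. number of points removed by a
#' denoising step) goes in `metadata`.
#'
#' @slot coords numeric matrix with columns x, y, z (metres).
#' @slot pointData data.frame with zero rows or one row per point.
#' @slot metadata named list of provenance entries.
#' @export
setClass("PointCloud",
  representation(coords = "matrix", pointData = "data.frame",
                 metadata = "list"),
  prototype(coords = matrix(numeric(0), 0, 3,
                            dimnames = list(NULL, c("x", "y", "z"))),
            pointData = data.frame(), metadata = list()))

setValidity("PointCloud", function(object) {
  cc <- object@coords
  if (!is.numeric(cc) || ncol(cc) != 3)
    return("coords must be a numeric matrix with 3 columns (x, y, z)")
  if (!identical(colnames(cc), c("x", "y", "z")))
    return("coords columns must be named x, y, z")
  if (nrow(cc) > 0 && any(!is.finite(cc)))
    return("coordinates must be finite")
  pd <- object@pointData
  if (nrow(pd) != 0 && nrow(pd) != nrow(cc))
    return("pointData must have zero rows or one row per point")
  TRUE
})

#' Construct a PointCloud
#'
#' @param coords an n x 3 numeric matrix, or a data.frame containing columns
#'   `x`, `y`, `z` (extra columns become per-point attributes).
#' @param pointData optional data.frame of per-point attributes.
#' @param metadata named list of provenance entries.
#' @return a [PointCloud-class] object.
#' @examples
#' pc <- PointCloud(cbind(x = runif(10), y = runif(10), z = 0))
#' npoints(pc)
#' @export
PointCloud <- function(coords, pointData = NULL, metadata = list()) {
  if (is.data.frame(coords)) {
    stopifnot(all(c("x", "y", "z") %in% names(coords)))
    extra <- coords[setdiff(names(coords), c("x", "y", "z"))]
    if (is.null(pointData) && ncol(extra) > 0) pointData <- extra
    coords <- as.matrix(coords[c("x", "y", "z")])
  }
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y", "z")
  if (is.null(pointData)) pointData <- data.frame()
  new("PointCloud", coords = coords, pointData = pointData,
      metadata = metadata)
}

#' GroundModel: a TIN digital elevation model
#'
#' A Delaunay triangulation of classified ground points with linear
#' (barycentric) interpolation inside the convex hull. Outside the hull the
#' plane of the triangle incident to the nearest vertex is extended
#' (nearest-facet extrapolation).
#'
#' @slot points numeric matrix (x, y, z) of the ground points.
#' @slot triangles integer matrix, one row per facet, vertex indices.
#' @export
setClass("GroundModel",
  representation(points = "matrix", triangles = "matrix"))

setValidity("GroundModel", function(object) {
  if (ncol(object@points) != 3) return("points must have 3 columns")
  if (ncol(object@triangles) != 3) return("triangles must have 3 columns")
  if (nrow(object@triangles) > 0 &&
      (max(object@triangles) > nrow(object@points) ||
       min(object@triangles) < 1))
    return("triangle vertex indices out of range")
  TRUE
})

#' ForestStand: a plot's tree table plus plot geometry
#'
#' The tree table holds one row per stem with columns `tree_id`, `species`,
#' `x`, `y` (metres, plot-relative), `dbh` (cm), `height` (m) and optionally
#' `source` ("field" or "bls") and `core` (eligible as a central tree after
#' edge buffering).
#'
#' @slot trees data.frame as described above.
#' @slot plotSize numeric, side length of the square plot in metres.
#' @slot metadata named list (generator spec, buffer width used, ...).
#' @export
setClass("ForestStand",
  representation(trees = "data.frame", plotSize = "numeric",
                 metadata = "list"))

setValidity("ForestStand", function(object) {
  tr <- object@trees
  need <- c("tree_id", "species", "x", "y", "dbh", "height")
  if (!all(need %in% names(tr)))
    return(paste("trees must contain columns:", paste(need, collapse = ", ")))
  if (length(object@plotSize) != 1 || object@plotSize <= 0)
    return("plotSize must be a single positive number")
  if (anyDuplicated(tr$tree_id)) return("tree ids must be unique")
  if (nrow(tr) > 0) {
    if (any(tr$x < -1e-9 | tr$x > object@plotSize + 1e-9 |
            tr$y < -1e-9 | tr$y > object@plotSize + 1e-9))
      return("tree positions must lie within [0, plotSize]^2")
    if (any(tr$dbh <= 0)) return("dbh must be positive")
    if (any(tr$height <= 0)) return("height must be positive")
  }
  TRUE
})

#' Construct a ForestStand
#'
#' @param trees data.frame with columns `tree_id`, `species`, `x`, `y`,
#'   `dbh`, `height` (and optionally `source`).
#' @param plotSize side of the square plot in metres.
#' @param metadata named list.
#' @return a [ForestStand-class] object.
#' @export
ForestStand <- function(trees, plotSize, metadata = list()) {
  trees <- as.data.frame(trees)
  new("ForestStand", trees = trees, plotSize = as.numeric(plotSize),
      metadata = metadata)
}

setMethod("show", "PointCloud", function(object) {
  cat(sprintf("PointCloud with %d points\n", nrow(object@coords)))
  if (nrow(object@coords) > 0) {
    rg <- apply(object@coords, 2, range)
    cat(sprintf("  x: [%.3f, %.3f]  y: [%.3f, %.3f]  z: [%.3f, %.3f]\n",
                rg[1, 1], rg[2, 1], rg[1, 2], rg[2, 2], rg[1, 3], rg[2, 3]))
  }
  if (ncol(object@pointData) > 0)
    cat("  attributes:", paste(names(object@pointData), collapse = ", "), "\n")
})

setMethod("show", "GroundModel", function(object) {
  cat(sprintf("TIN GroundModel: %d ground points, %d facets\n",
              nrow(object@points), nrow(object@triangles)))
})

setMethod("show", "ForestStand", function(object) {
  tr <- object@trees
  cat(sprintf("ForestStand: %d trees in a %g m x %g m plot\n",
              nrow(tr), object@plotSize, object@plotSize))
  if (nrow(tr) > 0)
    cat(sprintf("  %d species; DBH %.1f-%.1f cm; height %.1f-%.1f m\n",
                length(unique(tr$species)), min(tr$dbh), max(tr$dbh),
                min(tr$height), max(tr$height)))
})
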