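#' Number of points in a cloud
#' @param x a [PointCloud-class].
#' @return integer point count.
#' @export
setGeneric("npoints", function(x) standardGeneric("npoints"))

#' @rdname npoints
#' @export
setMethod("npoints", "PointCloud", function(x) nrow(x@coords))

#' Coordinate matrix of a cloud
#' @param x a [PointCloud-class].
#' @return n x 3 numeric matrix (x, y, z in metres).
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "PointCloud", function(x) x@coords)

#' Per-point attribute table
#' @param x a [PointCloud-class].
#' @return data.frame with one row per point (possibly zero columns).
#' @export
setGeneric("pointData", function(x) standardGeneric("pointData"))

#' @rdname pointData
#' @export
setMethod("pointData", "PointCloud", function(x) x@pointData)

#' Tree table of a stand
#' @param x a [ForestStand-class].
#' @return data.frame, one row per tree.
#' @export
setGeneric("treeData", function(x) standardGeneric("treeData"))

#' @rdname treeData
#' @export
setMethod("treeData", "ForestStand", function(x) x@trees)

#' Plot side length
#' @param x a [ForestStand-class].
#' @return numeric, metres.
#' @export
setGeneric("plotSize", function(x) standardGeneric("plotSize"))

#' @rdname plotSize
#' @export
setMethod("plotSize", "ForestStand", function(x) x@plotSize)

#' Provenance metadata
#' @param x a [PointCloud-class] or [ForestStand-class].
#' @return named list.
#' @export
setGeneric("cloudMetadata", function(x) standardGeneric("cloudMetadata"))

#' @rdname cloudMetadata
#' @export
setMethod("cloudMetadata", "PointCloud", function(x) x@metadata)

#' @rdname cloudMetadata
#' @export
setMethod("cloudMetadata", "ForestStand", function(x) x@metadata)

# internal: subset a cloud by point index, keeping attributes aligned
.subsetCloud <- function(cloud, idx, metadata = cloud@metadata) {
  pd <- cloud@pointData
  if (nrow(pd) > 0) pd <- pd[idx, , drop = FALSE]
  rownames(pd) <- NULL
  new("PointCloud", coords = cloud@coords[idx, , drop = FALSE],
      pointData = pd, metadata = metadata)
}
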