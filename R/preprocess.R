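# Pre-processing chain: crop -> thin -> denoise -> ground/non-ground ->
# TIN DEM -> height normalization.

#' Clip a cloud to a quadrilateral plot
#'
#' Keeps exactly the points inside (boundary inclusive) the quadrilateral
#' given by four corner points in order around the plot, mirroring plot
#' clipping from four field marker points.
#'
#' @param cloud a [PointCloud-class].
#' @param corners 4 x 2 matrix of (x, y) corners in traversal order.
#' @return the clipped [PointCloud-class].
#' @export
cropToPlot <- function(cloud, corners) {
  stopifnot(is(cloud, "PointCloud"))
  corners <- as.matrix(corners)
  if (nrow(corners) != 4 || ncol(corners) != 2)
    stop("corners must be a 4 x 2 matrix")
  # degenerate if polygon area vanishes
  xs <- corners[, 1]; ys <- corners[, 2]
  area <- 0.5 * abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys))
  if (area < 1e-12) stop("degenerate plot corners")
  cc <- coords(cloud)
  inside <- .pointInPolygon(cc[, "x"], cc[, "y"], xs, ys)
  .subsetCloud(cloud, which(inside))
}

# even-odd ray casting with an explicit boundary-inclusive on-segment test
.pointInPolygon <- function(px, py, vx, vy, eps = 1e-9) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  onEdge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    within <- px >= pmin(xi, xj) - eps & px <= pmax(xi, xj) + eps &
      py >= pmin(yi, yj) - eps & py <= pmax(yi, yj) + eps
    onEdge <- onEdge | (abs(cross) <= eps * (1 + abs(xj - xi) + abs(yj - yi)) &
                          within)
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | onEdge
}

#' Uniform random thinning of a point cloud
#'
#' Retains `round(retainFraction * n)` points drawn uniformly without
#' replacement (every point equally likely to survive); survivors keep their
#' original order, and the thinning does not alter the positional
#' distribution of the cloud.
#'
#' @param cloud a [PointCloud-class].
#' @param retainFraction fraction of points to keep, in (0, 1]; the
#'   conventional 80 % corresponds to 0.8.
#' @param seed integer seed.
#' @return the thinned [PointCloud-class].
#' @export
randomSample <- function(cloud, retainFraction = 0.8, seed = NULL) {
  stopifnot(is(cloud, "PointCloud"))
  n <- npoints(cloud)
  if (n == 0) stop("empty cloud")
  if (retainFraction <= 0 || retainFraction > 1)
    stop("retainFraction must be in (0, 1]")
  m <- round(retainFraction * n)
  .withSeed(seed, {
    keep <- sort(sample.int(n, m))
    .subsetCloud(cloud, keep)
  })
}

#' Statistical outlier removal (SOR)
#'
#' Computes each point's mean distance to its `k` nearest neighbours and
#' removes points whose mean distance exceeds the global mean plus `nSigma`
#' standard deviations of that statistic — the conventional k = 10,
#' sigma = 2 setting.
#'
#' @param cloud a [PointCloud-class] with more than `k` points.
#' @param k neighbourhood size.
#' @param nSigma standard-deviation multiplier of the global threshold.
#' @return the denoised [PointCloud-class]; `cloudMetadata()$sorRemoved`
#'   holds the number of points removed.
#' @export
sorDenoise <- function(cloud, k = 10, nSigma = 2) {
  stopifnot(is(cloud, "PointCloud"))
  n <- npoints(cloud)
  if (k >= n) stop("k must be smaller than the number of points")
  cc <- coords(cloud)
  nn <- .knn(cc, cc, k, self = seq_len(n))
  md <- rowMeans(nn$dist)
  thr <- mean(md) + nSigma * stats::sd(md)
  # relative slack so numerically-equal statistics never trip the threshold
  keep <- which(md <= thr + 1e-9 * (abs(thr) + mean(md)))
  md2 <- cloud@metadata
  md2$sorRemoved <- n - length(keep)
  .subsetCloud(cloud, keep, metadata = md2)
}

#' Classify ground and non-ground points
#'
#' A grid-based lower-envelope classifier standing in for a cloth-simulation
#' filter: the cloud is binned into `cellSize` cells, the envelope of a cell
#' is the minimum z over its 3 x 3 cell neighbourhood, and points within
#' `heightTolerance` of the envelope are labelled ground (LAS class 2),
#' everything else non-ground (class 1). Every point receives a label.
#'
#' @param cloud a non-empty [PointCloud-class].
#' @param cellSize grid cell size (m).
#' @param heightTolerance vertical tolerance above the envelope (m).
#' @return the same cloud with a `classification` point attribute.
#' @export
classifyGround <- function(cloud, cellSize = 0.5, heightTolerance = 0.2) {
  stopifnot(is(cloud, "PointCloud"))
  n <- npoints(cloud)
  if (n == 0) stop("empty cloud")
  cc <- coords(cloud)
  ix <- floor(cc[, "x"] / cellSize)
  iy <- floor(cc[, "y"] / cellSize)
  key <- paste(ix, iy)
  cellMin <- tapply(cc[, "z"], key, min)
  # envelope: min over the 3 x 3 neighbourhood of each occupied cell
  cells <- do.call(rbind, strsplit(names(cellMin), " "))
  cx <- as.numeric(cells[, 1]); cy <- as.numeric(cells[, 2])
  env <- cellMin
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    nb <- cellMin[paste(cx + dx, cy + dy)]
    env <- pmin(env, nb, na.rm = TRUE)
  }
  names(env) <- names(cellMin)
  ground <- cc[, "z"] <= env[key] + heightTolerance
  pd <- cloud@pointData
  if (nrow(pd) == 0) pd <- data.frame(row.names = seq_len(n))
  pd$classification <- ifelse(ground, 2L, 1L)
  new("PointCloud", coords = cc, pointData = pd, metadata = cloud@metadata)
}

#' Extract the ground-labelled subset of a cloud
#'
#' @param cloud a classified [PointCloud-class] (see [classifyGround()]).
#' @return a [PointCloud-class] of the class-2 points.
#' @export
groundPoints <- function(cloud) {
  stopifnot(is(cloud, "PointCloud"))
  cl <- pointData(cloud)$classification
  if (is.null(cl)) stop("cloud has no classification attribute")
  .subsetCloud(cloud, which(cl == 2L))
}

#' Build a TIN digital elevation model from ground points
#'
#' Delaunay-triangulates the ground points in the horizontal plane; queries
#' inside the convex hull are interpolated linearly over the containing
#' facet, queries outside extend the plane of a facet incident to the
#' nearest ground point (nearest-facet extrapolation).
#'
#' @param ground a [PointCloud-class] of ground points (>= 3, not all
#'   collinear). Duplicate (x, y) locations keep their lowest z.
#' @return a [GroundModel-class].
#' @export
buildDEM <- function(ground) {
  stopifnot(is(ground, "PointCloud"))
  cc <- coords(ground)
  if (nrow(cc) < 3) stop("need at least 3 ground points")
  # deduplicate horizontal locations, keeping the lowest elevation
  o <- order(cc[, "x"], cc[, "y"], cc[, "z"])
  cc <- cc[o, , drop = FALSE]
  dup <- duplicated(round(cc[, c("x", "y")], 9))
  cc <- cc[!dup, , drop = FALSE]
  if (nrow(cc) < 3) stop("need at least 3 distinct ground locations")
  tri <- .delaunay(cc[, c("x", "y")])
  new("GroundModel", points = cc, triangles = tri)
}

#' Interpolate terrain elevation from a TIN
#'
#' @param dem a [GroundModel-class].
#' @param x,y query coordinates (vectors of equal length).
#' @return numeric vector of terrain elevations.
#' @export
demElevation <- function(dem, x, y) {
  stopifnot(is(dem, "GroundModel"))
  pts <- dem@points; tri <- dem@triangles
  nq <- length(x)
  out <- rep(NA_real_, nq)
  ax <- pts[tri[, 1], 1]; ay <- pts[tri[, 1], 2]; az <- pts[tri[, 1], 3]
  bx <- pts[tri[, 2], 1]; by <- pts[tri[, 2], 2]; bz <- pts[tri[, 2], 3]
  cx <- pts[tri[, 3], 1]; cy <- pts[tri[, 3], 2]; cz <- pts[tri[, 3], 3]
  den <- (by - cy) * (ax - cx) + (cx - bx) * (ay - cy)
  bary <- function(t, qx, qy) {
    l1 <- ((by[t] - cy[t]) * (qx - cx[t]) + (cx[t] - bx[t]) * (qy - cy[t])) /
      den[t]
    l2 <- ((cy[t] - ay[t]) * (qx - cx[t]) + (ax[t] - cx[t]) * (qy - cy[t])) /
      den[t]
    cbind(l1, l2, 1 - l1 - l2)
  }
  # facets incident to each vertex: the containing facet of a query is
  # almost always incident to one of its nearest vertices
  inc <- split(rep(seq_len(nrow(tri)), 3), as.vector(tri))
  kv <- min(3L, nrow(pts))
  nn <- .knn(cbind(x, y), pts[, 1:2, drop = FALSE], kv)
  unassigned <- integer(0)
  for (q in seq_len(nq)) {
    cand <- unique(unlist(inc[as.character(nn$idx[q, ])], use.names = FALSE))
    cand <- cand[abs(den[cand]) >= 1e-14]
    hit <- FALSE
    if (length(cand) > 0) {
      l <- bary(cand, x[q], y[q])
      ok <- which(l[, 1] >= -1e-9 & l[, 2] >= -1e-9 & l[, 3] >= -1e-9)
      if (length(ok) > 0) {
        t <- cand[ok[1]]
        lo <- l[ok[1], ]
        out[q] <- lo[1] * az[t] + lo[2] * bz[t] + lo[3] * cz[t]
        hit <- TRUE
      }
    }
    if (!hit) unassigned <- c(unassigned, q)
  }
  if (length(unassigned) > 0) {
    # full scan for queries missed by the incidence shortcut
    still <- unassigned
    unassigned <- integer(0)
    for (q in still) {
      valid <- which(abs(den) >= 1e-14)
      l <- bary(valid, x[q], y[q])
      ok <- which(l[, 1] >= -1e-9 & l[, 2] >= -1e-9 & l[, 3] >= -1e-9)
      if (length(ok) > 0) {
        t <- valid[ok[1]]
        out[q] <- l[ok[1], 1] * az[t] + l[ok[1], 2] * bz[t] +
          l[ok[1], 3] * cz[t]
      } else unassigned <- c(unassigned, q)
    }
  }
  if (length(unassigned) > 0) {
    # outside the hull: extend the plane of a facet at the nearest vertex
    nn <- .knn(cbind(x[unassigned], y[unassigned]), pts[, 1:2], 1)
    for (i in seq_along(unassigned)) {
      v <- nn$idx[i, 1]
      t <- which(tri[, 1] == v | tri[, 2] == v | tri[, 3] == v)[1]
      if (is.na(t)) { out[unassigned[i]] <- pts[v, 3]; next }
      if (abs(den[t]) < 1e-14) { out[unassigned[i]] <- pts[v, 3]; next }
      l1 <- ((by[t] - cy[t]) * (x[unassigned[i]] - cx[t]) +
               (cx[t] - bx[t]) * (y[unassigned[i]] - cy[t])) / den[t]
      l2 <- ((cy[t] - ay[t]) * (x[unassigned[i]] - cx[t]) +
               (ax[t] - cx[t]) * (y[unassigned[i]] - cy[t])) / den[t]
      out[unassigned[i]] <- l1 * az[t] + l2 * bz[t] + (1 - l1 - l2) * cz[t]
    }
  }
  out
}

#' Normalize point heights against a terrain model
#'
#' Subtracts the interpolated terrain elevation from each point's z, leaving
#' horizontal coordinates (and thus the spatial distribution of trees)
#' unchanged.
#'
#' @param cloud a [PointCloud-class].
#' @param dem a [GroundModel-class] covering the cloud's horizontal extent
#'   (points outside the hull use nearest-facet extrapolation).
#' @return the height-normalized [PointCloud-class].
#' @export
normalizeHeights <- function(cloud, dem) {
  stopifnot(is(cloud, "PointCloud"), is(dem, "GroundModel"))
  cc <- coords(cloud)
  z <- demElevation(dem, cc[, "x"], cc[, "y"])
  cc[, "z"] <- cc[, "z"] - z
  new("PointCloud", coords = cc, pointData = cloud@pointData,
      metadata = cloud@metadata)
}

#' Read / write XYZ point-cloud text files
#'
#' Plain CSV with columns `x`, `y`, `z` plus any per-point attributes.
#'
#' @param path file path.
#' @return for `readXYZ`, a [PointCloud-class].
#' @export
readXYZ <- function(path) {
  d <- utils::read.csv(path)
  PointCloud(d)
}

#' @rdname readXYZ
#' @param cloud a [PointCloud-class] to write.
#' @export
writeXYZ <- function(cloud, path) {
  stopifnot(is(cloud, "PointCloud"))
  d <- as.data.frame(coords(cloud))
  pd <- pointData(cloud)
  if (ncol(pd) > 0) d <- cbind(d, pd)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
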