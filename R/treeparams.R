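# Individual-tree parameter extraction from normalized point clouds.

# single-linkage radius clustering in the plane with grid buckets;
# returns an integer label per row (clusters are chains of points closer
# than eps)
.radiusCluster <- function(xy, eps) {
  n <- nrow(xy)
  ix <- floor(xy[, 1] / eps); iy <- floor(xy[, 2] / eps)
  key <- paste(ix, iy)
  cellOf <- split(seq_len(n), key)
  labels <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (labels[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    labels[s] <- cur
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      cand <- integer(0)
      for (dx in -1:1) for (dy in -1:1) {
        cl <- cellOf[[paste(ix[p] + dx, iy[p] + dy)]]
        if (!is.null(cl)) cand <- c(cand, cl)
      }
      cand <- cand[labels[cand] == 0L]
      if (length(cand) == 0) next
      d2 <- (xy[cand, 1] - xy[p, 1])^2 + (xy[cand, 2] - xy[p, 2])^2
      hit <- cand[d2 <= eps^2]
      if (length(hit) > 0) {
        labels[hit] <- cur
        queue <- c(queue, hit)
      }
    }
  }
  labels
}

#' Segment a normalized plot cloud into individual trees
#'
#' Trunk detection by density clustering of the points in a horizontal
#' height band (trunks are dense, well-separated clusters at stem height),
#' followed by assignment of every point to the trunk with the nearest
#' horizontal axis. This is a deliberately simple trunk-based segmentation:
#' it does not attempt shortest-path crown delineation.
#'
#' @param cloud a height-normalized [PointCloud-class].
#' @param band height band (m) used for trunk detection.
#' @param clusterRadius linkage radius (m) of the trunk clustering.
#' @param minCluster minimum points for a cluster to count as a trunk.
#' @return a list of [PointCloud-class], one per detected tree;
#'   each carries `cloudMetadata()$treeId` and the trunk axis position.
#' @export
segmentTrees <- function(cloud, band = c(1.0, 2.0), clusterRadius = 0.3,
                         minCluster = 15) {
  stopifnot(is(cloud, "PointCloud"))
  cc <- coords(cloud)
  inBand <- which(cc[, "z"] >= band[1] & cc[, "z"] <= band[2])
  if (length(inBand) == 0) stop("no points in the trunk-detection band")
  lab <- .radiusCluster(cc[inBand, c("x", "y"), drop = FALSE], clusterRadius)
  sizes <- table(lab)
  trunkLabs <- as.integer(names(sizes)[sizes >= minCluster])
  if (length(trunkLabs) == 0) stop("no trunk clusters found")
  axes <- t(vapply(trunkLabs, function(l) {
    idx <- inBand[lab == l]
    c(mean(cc[idx, "x"]), mean(cc[idx, "y"]))
  }, numeric(2)))
  nn <- .knn(cc[, c("x", "y"), drop = FALSE], axes, 1)
  assign <- nn$idx[, 1]
  lapply(seq_len(nrow(axes)), function(i) {
    sub <- .subsetCloud(cloud, which(assign == i))
    sub@metadata <- c(sub@metadata,
                      list(treeId = i, axis = axes[i, ]))
    sub
  })
}

# algebraic (Kasa) circle fit: minimises sum((x^2+y^2) + D x + E y + F)^2
.fitCircleKasa <- function(x, y) {
  A <- cbind(x, y, 1)
  b <- -(x^2 + y^2)
  sol <- tryCatch(unname(qr.solve(A, b, tol = 1e-12)),
                  error = function(e) NULL)
  if (is.null(sol)) stop("degenerate slice: points are collinear")
  cx <- -sol[1] / 2; cy <- -sol[2] / 2
  r2 <- cx^2 + cy^2 - sol[3]
  if (!is.finite(r2) || r2 <= 0) stop("degenerate slice: no valid circle")
  list(cx = cx, cy = cy, r = sqrt(r2))
}

# Gauss-Newton geometric refinement of (cx, cy, r)
.refineCircle <- function(x, y, fit, iters = 25) {
  cx <- fit$cx; cy <- fit$cy; r <- fit$r
  for (it in seq_len(iters)) {
    dx <- x - cx; dy <- y - cy
    d <- sqrt(dx^2 + dy^2)
    d[d < 1e-12] <- 1e-12
    resid <- d - r
    J <- cbind(-dx / d, -dy / d, -1)
    step <- tryCatch(qr.solve(J, -resid, tol = 1e-12),
                     error = function(e) NULL)
    if (is.null(step)) break
    cx <- cx + step[1]; cy <- cy + step[2]; r <- r + step[3]
    if (max(abs(step)) < 1e-12) break
  }
  list(cx = cx, cy = cy, r = r)
}

# slice extraction + circle fit shared by extractDBH / extractPosition
.sliceCircle <- function(cloud, sliceLow, sliceHigh, minPoints,
                         method = c("kasa", "geometric")) {
  method <- match.arg(method)
  cc <- coords(cloud)
  sel <- cc[, "z"] >= sliceLow & cc[, "z"] <= sliceHigh
  if (sum(sel) < minPoints)
    stop(sprintf("only %d points in the %.2f-%.2f m slice (min %d)",
                 sum(sel), sliceLow, sliceHigh, minPoints))
  x <- cc[sel, "x"]; y <- cc[sel, "y"]
  fit <- .fitCircleKasa(x, y)
  if (method == "geometric") fit <- .refineCircle(x, y, fit)
  fit
}

#' Extract DBH from a breast-height slice
#'
#' Takes the 10 cm slice between `sliceLow` and `sliceHigh`, projects it to
#' the horizontal plane and fits a circle by least squares. The default is
#' the closed-form algebraic (Kasa) fit, exact on noiseless cylinders; an
#' iterative geometric refinement is available via `method = "geometric"`.
#'
#' @param tree a [PointCloud-class] of one normalized tree.
#' @param sliceLow,sliceHigh slice bounds (m) around breast height (1.3 m).
#' @param minPoints minimum slice occupancy for a valid fit.
#' @param method `"kasa"` or `"geometric"`.
#' @return DBH in cm (twice the fitted radius).
#' @examples
#' pc <- generateStemCloud(stemCloudSpec(dbh = 30, height = 10, seed = 1))
#' extractDBH(pc)  # 30 to numerical precision
#' @export
extractDBH <- function(tree, sliceLow = 1.25, sliceHigh = 1.35,
                       minPoints = 10, method = c("kasa", "geometric")) {
  stopifnot(is(tree, "PointCloud"))
  fit <- .sliceCircle(tree, sliceLow, sliceHigh, minPoints, method)
  200 * fit$r
}

#' Extract tree height
#'
#' Height is the absolute difference between the highest and lowest points
#' of the tree's cloud in the vertical direction.
#'
#' @param tree a non-empty [PointCloud-class].
#' @return height in m.
#' @export
extractHeight <- function(tree) {
  stopifnot(is(tree, "PointCloud"))
  z <- coords(tree)[, "z"]
  if (length(z) == 0) stop("empty tree cloud")
  max(z) - min(z)
}

#' Extract the stem-base position
#'
#' The relative coordinate of a tree is the centre of its root: the
#' horizontal centroid of the points within `baseBand` of the lowest point.
#' If fewer than 3 such points exist, the centre of the breast-height
#' slice circle is used instead.
#'
#' @param tree a non-empty [PointCloud-class].
#' @param baseBand thickness (m) of the base layer above the lowest point.
#' @param sliceLow,sliceHigh,minPoints fallback slice-circle parameters.
#' @return c(x, y) in m.
#' @export
extractPosition <- function(tree, baseBand = 0.3, sliceLow = 1.25,
                            sliceHigh = 1.35, minPoints = 10) {
  stopifnot(is(tree, "PointCloud"))
  cc <- coords(tree)
  if (nrow(cc) == 0) stop("empty tree cloud")
  base <- cc[, "z"] <= min(cc[, "z"]) + baseBand
  if (sum(base) >= 3)
    return(c(x = mean(cc[base, "x"]), y = mean(cc[base, "y"])))
  fit <- .sliceCircle(tree, sliceLow, sliceHigh, minPoints)
  c(x = fit$cx, y = fit$cy)
}

#' Extract a tree table from segmented tree clouds
#'
#' Runs [extractDBH()], [extractHeight()] and [extractPosition()] on each
#' tree cloud and assembles a scanner-derived tree table. Trees whose
#' fitted DBH falls below the census minimum are dropped (with a message),
#' mirroring the DBH >= 5 cm census rule; trees whose slice fit fails are
#' dropped likewise.
#'
#' @param trees list of [PointCloud-class] from [segmentTrees()].
#' @param censusMin minimum DBH (cm) for inclusion.
#' @param ... passed to [extractDBH()].
#' @return data.frame with columns `tree_id`, `species` (NA), `x`, `y`,
#'   `dbh`, `height`, `source = "bls"`.
#' @export
extractTreeParameters <- function(trees, censusMin = 5, ...) {
  rows <- lapply(trees, function(tc) {
    id <- cloudMetadata(tc)$treeId %||% NA_integer_
    dbh <- tryCatch(extractDBH(tc, ...), error = function(e) NA_real_)
    if (is.na(dbh)) return(NULL)
    pos <- extractPosition(tc)
    data.frame(tree_id = id, species = NA_character_,
               x = pos[["x"]], y = pos[["y"]], dbh = dbh,
               height = extractHeight(tc), source = "bls",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no valid trees extracted")
  low <- out$dbh < censusMin
  if (any(low))
    message(sprintf("dropping %d tree(s) with DBH below %g cm", sum(low),
                    censusMin))
  out <- out[!low, , drop = FALSE]
  rownames(out) <- NULL
  out
}
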