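# Incremental Bowyer-Watson Delaunay triangulation in the plane.
# Plot-scale inputs (hundreds to a few thousand vertices), so the O(n * T)
# vectorised cavity search is adequate without spatial indexing.

.circumcircle <- function(ax, ay, bx, by, cx, cy) {
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  list(x = ux, y = uy, r2 = (ax - ux)^2 + (ay - uy)^2, degenerate = d == 0)
}

# xy: n x 2 matrix of distinct points. Returns an m x 3 integer matrix of
# triangle vertex indices; errors if the input is degenerate (all collinear).
.delaunay <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 3) stop("need at least 3 points to triangulate")
  if (anyDuplicated(round(xy, 12)))
    stop("coincident points cannot be triangulated")
  # centre and scale for conditioning
  ctr <- colMeans(xy)
  sc <- max(apply(xy, 2, function(v) diff(range(v))), 1e-12)
  px <- (xy[, 1] - ctr[1]) / sc
  py <- (xy[, 2] - ctr[2]) / sc
  # super-triangle well outside the unit-scaled data
  big <- 64
  px <- c(px, 0, -big, big)
  py <- c(py, big, -big, -big)
  sup <- n + 1:3

  v1 <- sup[1]; v2 <- sup[2]; v3 <- sup[3]
  cc <- .circumcircle(px[v1], py[v1], px[v2], py[v2], px[v3], py[v3])
  tri <- matrix(c(v1, v2, v3), 1, 3)
  ccx <- cc$x; ccy <- cc$y; ccr2 <- cc$r2

  for (p in seq_len(n)) {
    d2 <- (px[p] - ccx)^2 + (py[p] - ccy)^2
    bad <- which(d2 < ccr2 * (1 + 1e-12) + 1e-14)
    if (length(bad) == 0) stop("triangulation failed (numerical degeneracy)")
    # cavity boundary = edges of bad triangles that appear exactly once
    e <- rbind(tri[bad, c(1, 2), drop = FALSE],
               tri[bad, c(2, 3), drop = FALSE],
               tri[bad, c(3, 1), drop = FALSE])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    once <- key %in% names(which(table(key) == 1))
    boundary <- e[once, , drop = FALSE]
    tri <- tri[-bad, , drop = FALSE]
    ccx <- ccx[-bad]; ccy <- ccy[-bad]; ccr2 <- ccr2[-bad]
    if (nrow(boundary) > 0) {
      newt <- cbind(boundary, p)
      keep <- rep(TRUE, nrow(newt))
      nx <- ny <- nr <- numeric(nrow(newt))
      for (i in seq_len(nrow(newt))) {
        cc <- .circumcircle(px[newt[i, 1]], py[newt[i, 1]],
                            px[newt[i, 2]], py[newt[i, 2]],
                            px[newt[i, 3]], py[newt[i, 3]])
        if (cc$degenerate || !is.finite(cc$r2)) { keep[i] <- FALSE; next }
        nx[i] <- cc$x; ny[i] <- cc$y; nr[i] <- cc$r2
      }
      tri <- rbind(tri, newt[keep, , drop = FALSE])
      ccx <- c(ccx, nx[keep]); ccy <- c(ccy, ny[keep])
      ccr2 <- c(ccr2, nr[keep])
    }
  }
  real <- tri[, 1] <= n & tri[, 2] <= n & tri[, 3] <= n
  tri <- tri[real, , drop = FALSE]
  if (nrow(tri) == 0)
    stop("degenerate geometry: points are collinear")
  unname(tri)
}

# adjacency list (Voronoi neighbours = Delaunay edges) from a triangle matrix
.triAdjacency <- function(tri, n) {
  adj <- vector("list", n)
  e <- rbind(tri[, 1:2, drop = FALSE], tri[, 2:3, drop = FALSE],
             tri[, c(3, 1), drop = FALSE])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  for (i in seq_len(n)) {
    nb <- c(e[e[, 1] == i, 2], e[e[, 2] == i, 1])
    adj[[i]] <- sort(unique(nb))
  }
  adj
}
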