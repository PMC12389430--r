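# Spatial structure: edge buffer, neighbour units, and the four classical
# nearest-neighbour indices (uniform angle W, mingling M, dominance U,
# Hegyi competition CI), each computed over a central tree and its four
# nearest neighbours.

#' Partition a stand into core and buffer trees
#'
#' Generates a rectangular buffer belt of the given width along the plot
#' edge. Buffer trees serve only as neighbours; trees in the inner square
#' are eligible as central trees.
#'
#' @param stand a [ForestStand-class].
#' @param buffer belt width (m), less than half the plot side.
#' @return the stand with a logical `core` column added to its tree table.
#' @export
applyEdgeBuffer <- function(stand, buffer = 2.5) {
  stopifnot(is(stand, "ForestStand"))
  L <- plotSize(stand)
  if (buffer < 0 || buffer >= L / 2)
    stop("buffer must be non-negative and less than half the plot side")
  tr <- treeData(stand)
  tr$core <- tr$x >= buffer & tr$x <= L - buffer &
    tr$y >= buffer & tr$y <= L - buffer
  md <- stand@metadata
  md$buffer <- buffer
  ForestStand(tr, L, metadata = md)
}

#' Structure unit of one central tree
#'
#' Finds the `k` trees nearest (horizontal Euclidean distance) to the
#' central tree; ties are broken by ascending tree id. Coincident stems
#' (zero distance) are rejected. Azimuths use 0 deg = north (+y),
#' clockwise positive.
#'
#' @param stand a [ForestStand-class] with at least `k + 1` trees.
#' @param central tree id of the central tree.
#' @param k number of neighbours (4 in the classical formulation).
#' @return data.frame with one row per neighbour: `central_id`,
#'   `neighbor_id`, `distance` (m), `azimuth` (deg).
#' @export
findNeighbors <- function(stand, central, k = 4) {
  stopifnot(is(stand, "ForestStand"))
  tr <- treeData(stand)
  if (nrow(tr) < k + 1) stop("stand must contain at least k + 1 trees")
  tr <- tr[order(tr$tree_id), , drop = FALSE]
  ci <- match(central, tr$tree_id)
  if (is.na(ci)) stop("unknown central tree id")
  d <- sqrt((tr$x - tr$x[ci])^2 + (tr$y - tr$y[ci])^2)
  d[ci] <- Inf
  if (any(d == 0))
    stop("coincident stems (zero distance) in the stand")
  o <- order(d, seq_len(nrow(tr)))[seq_len(k)]
  data.frame(central_id = tr$tree_id[ci],
             neighbor_id = tr$tree_id[o],
             distance = d[o],
             azimuth = .azimuth(tr$x[ci], tr$y[ci], tr$x[o], tr$y[o]),
             stringsAsFactors = FALSE)
}

#' Uniform angle index of one structure unit
#'
#' Sorts the neighbours by azimuth, forms the circular gaps between
#' successive neighbours, folds each gap to at most 180 deg (an angle
#' between two directions), and returns the fraction of gaps strictly
#' smaller than the standard angle. Values near 0.5 indicate random
#' placement, higher values clumping, lower values regularity.
#'
#' @param azimuth numeric vector of neighbour azimuths (deg).
#' @param alpha0 standard angle (deg); the classical value is 72 = 360/5.
#' @param foldReflex fold gaps over 180 deg to their explement (default);
#'   results are identical whenever no gap exceeds 180 deg.
#' @return Wi, on the grid {0, 0.25, 0.5, 0.75, 1} for 4 neighbours.
#' @examples
#' uniformAngle(c(0, 90, 180, 270))  # 0: perfectly even
#' uniformAngle(c(0, 60, 120, 180))  # 0.75
#' @export
uniformAngle <- function(azimuth, alpha0 = 72, foldReflex = TRUE) {
  if (any(is.na(azimuth))) stop("missing azimuths")
  a <- sort(azimuth %% 360)
  gaps <- diff(c(a, a[1] + 360))
  if (foldReflex) gaps <- pmin(gaps, 360 - gaps)
  mean(gaps < alpha0)
}

#' Mingling of one structure unit
#'
#' Fraction of neighbours belonging to a different species than the
#' central tree.
#'
#' @param centralSpecies species label of the central tree.
#' @param neighborSpecies species labels of the neighbours.
#' @return Mi in \[0, 1\].
#' @export
mingling <- function(centralSpecies, neighborSpecies) {
  if (is.na(centralSpecies) || any(is.na(neighborSpecies)))
    stop("missing species labels")
  mean(neighborSpecies != centralSpecies)
}

#' Dominance (neighbourhood comparison) of one structure unit
#'
#' Fraction of neighbours with strictly larger DBH than the central tree;
#' equal diameters do not count (ties are "not larger").
#'
#' @param centralDbh DBH of the central tree (cm).
#' @param neighborDbh DBH of the neighbours (cm).
#' @return Ui in \[0, 1\].
#' @export
dominance <- function(centralDbh, neighborDbh) {
  if (is.na(centralDbh) || any(is.na(neighborDbh)))
    stop("missing DBH values")
  mean(neighborDbh > centralDbh)
}

#' Hegyi competition index of one structure unit
#'
#' Sum over neighbours of the competitor-to-subject diameter ratio divided
#' by the intertree distance: CIi = sum_j (dj / di) / Lij. Unchanged by a
#' common rescaling of all diameters; halves when all distances double.
#'
#' @param centralDbh DBH of the central (subject) tree (cm), > 0.
#' @param neighborDbh DBH of the neighbours (cm).
#' @param distance intertree distances (m), > 0.
#' @return CIi (> 0 whenever all DBH are positive).
#' @examples
#' hegyi(20, c(10, 20, 30, 40), c(2, 4, 5, 8))  # 1.05
#' @export
hegyi <- function(centralDbh, neighborDbh, distance) {
  if (centralDbh <= 0) stop("central DBH must be positive")
  if (any(distance <= 0)) stop("distances must be positive")
  sum((neighborDbh / centralDbh) / distance)
}

#' Per-tree spatial structure indices for a stand
#'
#' Applies the edge buffer, builds the 4-nearest-neighbour structure unit
#' of every core tree (buffer trees act as neighbours only) and evaluates
#' W, U, M and CI for each.
#'
#' @param stand a [ForestStand-class].
#' @param k neighbours per structure unit.
#' @param buffer edge-buffer width (m).
#' @param alpha0 standard angle (deg) for W.
#' @return data.frame: `tree_id`, `species`, `dbh`, `W`, `U`, `M`, `CI`.
#' @export
spatialIndices <- function(stand, k = 4, buffer = 2.5, alpha0 = 72) {
  stopifnot(is(stand, "ForestStand"))
  stand <- applyEdgeBuffer(stand, buffer)
  tr <- treeData(stand)
  if (nrow(tr) < k + 1) stop("stand must contain at least k + 1 trees")
  core <- tr[tr$core, , drop = FALSE]
  if (nrow(core) == 0) stop("no core trees after edge buffering")
  dbhOf <- stats::setNames(tr$dbh, as.character(tr$tree_id))
  spOf <- stats::setNames(tr$species, as.character(tr$tree_id))
  rows <- lapply(seq_len(nrow(core)), function(i) {
    u <- findNeighbors(stand, core$tree_id[i], k)
    nid <- as.character(u$neighbor_id)
    data.frame(tree_id = core$tree_id[i], species = core$species[i],
               dbh = core$dbh[i],
               W = uniformAngle(u$azimuth, alpha0),
               U = dominance(core$dbh[i], dbhOf[nid]),
               M = mingling(core$species[i], spOf[nid]),
               CI = hegyi(core$dbh[i], dbhOf[nid], u$distance),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Five-grade distribution of a structure index
#'
#' With four neighbours, W, U and M take values on the grid
#' {0, 0.25, 0.5, 0.75, 1}; this tabulates the proportion of trees at each
#' grade (interval 0.25).
#'
#' @param values index values on the five-grade grid.
#' @return named numeric vector of proportions summing to 1.
#' @export
gradeDistribution <- function(values) {
  if (length(values) == 0) stop("no index values")
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  m <- match(round(values * 4) / 4, grid)
  if (any(is.na(m)) || any(abs(values * 4 - round(values * 4)) > 1e-9))
    stop("index values must lie on the grid {0, 0.25, 0.5, 0.75, 1}")
  p <- tabulate(m, 5) / length(values)
  stats::setNames(p, c("0", "0.25", "0.5", "0.75", "1"))
}

#' Plot-level summary of spatial structure indices
#'
#' @param indices output of [spatialIndices()].
#' @return list with `means` (mean W, U, M, CI over core central trees) and
#'   `grades` (five-grade distributions of W, U, M).
#' @export
plotStructureSummary <- function(indices) {
  list(means = c(W = mean(indices$W), U = mean(indices$U),
                 M = mean(indices$M), CI = mean(indices$CI)),
       grades = list(W = gradeDistribution(indices$W),
                     U = gradeDistribution(indices$U),
                     M = gradeDistribution(indices$M)))
}

#' Competition totals by diameter class
#'
#' Sums the per-tree Hegyi indices of the central trees falling in each
#' diameter class (optionally restricted to one species, e.g. the focal
#' species of a conservation survey), plus the overall mean CI. Empty
#' classes carry a zero total and are flagged.
#'
#' @param indices output of [spatialIndices()] (must carry `dbh`, `CI`).
#' @param species optional species label to subset the central trees.
#' @param width,origin diameter-class width and lower origin (cm).
#' @return list with `byClass` (data.frame: class, n, totalCI), `meanCI`,
#'   and `emptyClasses`.
#' @export
classCompetition <- function(indices, species = NULL, width = 10,
                             origin = 5) {
  x <- indices
  if (!is.null(species)) x <- x[x$species == species, , drop = FALSE]
  if (nrow(x) == 0) stop("no central trees in the requested subset")
  cls <- .dbhClassIndex(x$dbh, width, origin)
  ncls <- max(cls)
  tot <- vapply(seq_len(ncls), function(i) sum(x$CI[cls == i]), numeric(1))
  n <- tabulate(cls, ncls)
  list(byClass = data.frame(class = .romanLabels(ncls), n = n,
                            totalCI = tot, stringsAsFactors = FALSE),
       meanCI = mean(x$CI),
       emptyClasses = .romanLabels(ncls)[n == 0])
}

#' Voronoi (Delaunay) adjacency of a stand
#'
#' Builds the Delaunay triangulation of the stem positions; trees whose
#' Voronoi polygons share an edge are adjacent. Offered as an alternative
#' neighbour definition to the fixed 4-nearest-neighbour unit.
#'
#' @param stand a [ForestStand-class] with at least 4 non-collinear trees.
#' @return named list: for each tree id, the vector of adjacent tree ids.
#' @export
voronoiUnits <- function(stand) {
  stopifnot(is(stand, "ForestStand"))
  tr <- treeData(stand)
  tr <- tr[order(tr$tree_id), , drop = FALSE]
  if (nrow(tr) < 4) stop("need at least 4 trees")
  tri <- .delaunay(cbind(tr$x, tr$y))
  adj <- .triAdjacency(tri, nrow(tr))
  out <- lapply(adj, function(ix) tr$tree_id[ix])
  names(out) <- as.character(tr$tree_id)
  out
}

# diameter class index: 1 for [origin, origin + width), 2 for the next, ...
.dbhClassIndex <- function(dbh, width = 10, origin = 5) {
  if (any(dbh < origin))
    stop(sprintf("DBH below the class origin of %g cm", origin))
  pmax(1L, as.integer(floor((dbh - origin) / width)) + 1L)
}
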