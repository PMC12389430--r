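#' Specify a synthetic stand
#'
#' Parameter bundle for [generateStand()]. Defaults emulate the study
#' conditions this package was validated against: 25 m x 25 m mountain plots
#' holding a few dozen to a couple of hundred stems of 7-28 species, a
#' geometric abundance series with one dominant species, clustered-to-random
#' stem patterns, and an inverse-J DBH distribution with a 5 cm census
#' minimum.
#'
#' @param plotSize side of the square plot (m).
#' @param pattern stem point pattern: `"poisson"` (complete spatial
#'   randomness), `"cluster"` (Thomas-style parent-offspring process,
#'   offspring reflected at plot edges) or `"grid"` (regular lattice).
#' @param nTrees number of stems.
#' @param clusterParents number of cluster parents (pattern = "cluster").
#' @param clusterSd isotropic Gaussian offspring spread (m).
#' @param speciesCount number of species in the pool.
#' @param speciesAbundance `"geometric"` (species i has weight
#'   k(1-k)^(i-1), one dominant species) or `"uniform"`.
#' @param geometricK parameter k of the geometric series.
#' @param dbhRate rate (per cm) of the exponential DBH excess over `dbhMin`;
#'   smaller values give flatter (more large-tree) distributions.
#' @param dbhMin census minimum DBH (cm).
#' @param heightAllometry coefficients c(a, b) of H = a * DBH^b (m, DBH cm).
#' @param heightSd Gaussian noise on height (m); heights are floored at
#'   1.5 m so a breast-height slice always exists.
#' @param seed integer seed; fixed seed gives identical stands.
#' @return an object of class `standSpec`.
#' @seealso [generateStand()]
#' @export
standSpec <- function(plotSize = 25, pattern = c("poisson", "cluster", "grid"),
                      nTrees = 100, clusterParents = 6, clusterSd = 2,
                      speciesCount = 12,
                      speciesAbundance = c("geometric", "uniform"),
                      geometricK = 0.35, dbhRate = 0.08, dbhMin = 5,
                      heightAllometry = c(1.3, 0.6), heightSd = 0.5,
                      seed = NULL) {
  pattern <- match.arg(pattern)
  speciesAbundance <- match.arg(speciesAbundance)
  if (nTrees < 1) stop("nTrees must be >= 1")
  if (plotSize <= 0) stop("plotSize must be positive")
  if (clusterParents < 1) stop("clusterParents must be >= 1")
  if (speciesCount < 1) stop("speciesCount must be >= 1")
  if (dbhMin < 5) stop("minimum DBH below the 5 cm census rule")
  if (dbhRate <= 0) stop("dbhRate must be positive")
  structure(list(plotSize = plotSize, pattern = pattern, nTrees = nTrees,
                 clusterParents = clusterParents, clusterSd = clusterSd,
                 speciesCount = speciesCount,
                 speciesAbundance = speciesAbundance,
                 geometricK = geometricK, dbhRate = dbhRate, dbhMin = dbhMin,
                 heightAllometry = heightAllometry, heightSd = heightSd,
                 seed = seed),
            class = "standSpec")
}

.reflectIntoPlot <- function(v, L) {
  v <- v %% (2 * L)
  ifelse(v > L, 2 * L - v, v)
}

#' Generate a synthetic stand with known ground truth
#'
#' Draws stem positions from the requested point pattern, species labels
#' from the abundance model, DBH from an exponential distribution truncated
#' at the census minimum (producing the inverse-J diameter structure of
#' natural uneven-aged stands) and heights from a power-law allometry with
#' Gaussian noise.
#'
#' @param spec a [standSpec()].
#' @return a [ForestStand-class]; `treeData()` columns are `tree_id`,
#'   `species`, `x`, `y`, `dbh` (cm), `height` (m), `source = "field"`.
#' @examples
#' st <- generateStand(standSpec(pattern = "cluster", nTrees = 80, seed = 1))
#' st
#' @export
generateStand <- function(spec) {
  stopifnot(inherits(spec, "standSpec"))
  .withSeed(spec$seed, {
    n <- spec$nTrees
    L <- spec$plotSize
    if (spec$pattern == "grid") {
      side <- ceiling(sqrt(n))
      sp <- L / side
      g <- expand.grid(ix = seq_len(side), iy = seq_len(side))
      x <- (g$ix[seq_len(n)] - 0.5) * sp
      y <- (g$iy[seq_len(n)] - 0.5) * sp
    } else if (spec$pattern == "poisson") {
      x <- stats::runif(n, 0, L)
      y <- stats::runif(n, 0, L)
    } else {
      pxy <- cbind(stats::runif(spec$clusterParents, 0, L),
                   stats::runif(spec$clusterParents, 0, L))
      par <- sample.int(spec$clusterParents, n, replace = TRUE)
      x <- .reflectIntoPlot(pxy[par, 1] + stats::rnorm(n, 0, spec$clusterSd), L)
      y <- .reflectIntoPlot(pxy[par, 2] + stats::rnorm(n, 0, spec$clusterSd), L)
    }
    w <- switch(spec$speciesAbundance,
      geometric = spec$geometricK *
        (1 - spec$geometricK)^(seq_len(spec$speciesCount) - 1),
      uniform = rep(1, spec$speciesCount))
    speciesIdx <- sample.int(spec$speciesCount, n, replace = TRUE,
                             prob = w / sum(w))
    dbh <- spec$dbhMin + stats::rexp(n, rate = spec$dbhRate)
    a <- spec$heightAllometry[1]; b <- spec$heightAllometry[2]
    height <- pmax(a * dbh^b + stats::rnorm(n, 0, spec$heightSd), 1.5)
    trees <- data.frame(tree_id = seq_len(n),
                        species = sprintf("sp%02d", speciesIdx),
                        x = x, y = y, dbh = dbh, height = height,
                        source = "field", stringsAsFactors = FALSE)
    ForestStand(trees, L, metadata = list(spec = spec))
  })
}

#' Deterministic taxonomy for synthetic species labels
#'
#' Maps the generator's species labels onto synthetic genera (two species
#' per genus) and families (two genera per family), for exercising
#' [compositionSummary()].
#'
#' @param speciesCount number of species in the pool.
#' @return data.frame with columns `species`, `genus`, `family`.
#' @export
syntheticTaxonomy <- function(speciesCount) {
  i <- seq_len(speciesCount)
  data.frame(species = sprintf("sp%02d", i),
             genus = sprintf("gen%02d", ceiling(i / 2)),
             family = sprintf("fam%02d", ceiling(i / 4)),
             stringsAsFactors = FALSE)
}

#' Specify a synthetic stem point cloud
#'
#' @param dbh true DBH (cm), >= 5.
#' @param height true height (m), > 1.35 so the breast-height slice exists.
#' @param taper fractional radius decrease per metre of height.
#' @param radialNoiseSd Gaussian noise on the stem radius (m).
#' @param pointsPerM point density along the stem (points per metre).
#' @param crown optional list(`fraction`, `radius`, `n`): an ellipsoidal blob
#'   of `n` points centred at `fraction * height` with horizontal semi-axis
#'   `radius` (m) and vertical semi-axis `(1 - fraction) * height`.
#' @param center horizontal position c(x, y) of the stem axis (m).
#' @param lean optional lean as c(dx, dy): horizontal axis displacement per
#'   metre of height.
#' @param seed integer seed.
#' @return an object of class `stemCloudSpec`.
#' @export
stemCloudSpec <- function(dbh, height, taper = 0, radialNoiseSd = 0,
                          pointsPerM = 600, crown = NULL, center = c(0, 0),
                          lean = c(0, 0), seed = NULL) {
  if (dbh < 5) stop("dbh must be >= 5 cm")
  if (height <= 1.35) stop("height must exceed the 1.35 m slice top")
  if (radialNoiseSd < 0) stop("radialNoiseSd must be >= 0")
  if (pointsPerM <= 0) stop("pointsPerM must be positive")
  structure(list(dbh = dbh, height = height, taper = taper,
                 radialNoiseSd = radialNoiseSd, pointsPerM = pointsPerM,
                 crown = crown, center = center, lean = lean, seed = seed),
            class = "stemCloudSpec")
}

#' Generate a noisy cylindrical stem point cloud
#'
#' Samples points on the stem surface from the base (z = 0) to the tip; the
#' base and the exact tip are always included, so with no crown the highest
#' point sits at the true height. Radius follows `dbh/200 * (1 - taper * z)`
#' with Gaussian radial noise.
#'
#' @param spec a [stemCloudSpec()].
#' @return a [PointCloud-class]; `cloudMetadata()` carries the true DBH and
#'   height.
#' @examples
#' pc <- generateStemCloud(stemCloudSpec(dbh = 30, height = 12, seed = 1))
#' extractDBH(pc)
#' @export
generateStemCloud <- function(spec) {
  stopifnot(inherits(spec, "stemCloudSpec"))
  .withSeed(spec$seed, {
    n <- max(4L, round(spec$pointsPerM * spec$height))
    z <- c(0, spec$height, stats::runif(n - 2L, 0, spec$height))
    theta <- stats::runif(n, 0, 2 * pi)
    r0 <- spec$dbh / 200
    r <- pmax(r0 * (1 - spec$taper * z), 0.2 * r0)
    if (spec$radialNoiseSd > 0) r <- r + stats::rnorm(n, 0, spec$radialNoiseSd)
    x <- spec$center[1] + spec$lean[1] * z + r * cos(theta)
    y <- spec$center[2] + spec$lean[2] * z + r * sin(theta)
    if (!is.null(spec$crown)) {
      cf <- spec$crown$fraction %||% 0.75
      cr <- spec$crown$radius %||% 1.5
      cn <- spec$crown$n %||% 500L
      cz <- cf * spec$height
      rz <- max((1 - cf) * spec$height, 0.5)
      u <- matrix(stats::rnorm(3 * cn), cn, 3)
      u <- u / sqrt(rowSums(u^2)) * stats::runif(cn)^(1 / 3)
      x <- c(x, spec$center[1] + spec$lean[1] * cz + u[, 1] * cr)
      y <- c(y, spec$center[2] + spec$lean[2] * cz + u[, 2] * cr)
      z <- c(z, cz + u[, 3] * rz)
    }
    PointCloud(cbind(x = x, y = y, z = z),
               metadata = list(dbhTrue = spec$dbh, heightTrue = spec$height))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a full-plot point cloud from a stand
#'
#' Builds one stem cloud per tree at its true position plus an optional
#' ground grid on a planar (possibly tilted) terrain; stems are shifted so
#' their bases sit on the terrain. Per-point `treeId` (NA for ground) and
#' `trueGround` attributes carry the generator's ground truth for testing
#' segmentation and ground classification.
#'
#' @param stand a [ForestStand-class].
#' @param pointsPerM stem point density.
#' @param radialNoiseSd stem radial noise (m).
#' @param ground logical: add a ground grid?
#' @param groundSpacing ground grid spacing (m).
#' @param groundSlope c(sx, sy): terrain plane z = sx * x + sy * y.
#' @param crowns logical: add a small ellipsoidal crown per tree.
#' @param seed integer seed.
#' @return a [PointCloud-class] with `treeId` and `trueGround` attributes.
#' @export
generatePlotCloud <- function(stand, pointsPerM = 300, radialNoiseSd = 0.002,
                              ground = TRUE, groundSpacing = 0.25,
                              groundSlope = c(0, 0), crowns = FALSE,
                              seed = NULL) {
  stopifnot(is(stand, "ForestStand"))
  .withSeed(seed, {
    tr <- treeData(stand)
    parts <- lapply(seq_len(nrow(tr)), function(i) {
      crown <- if (crowns) list(fraction = 0.8,
                                radius = 0.8, n = 200L) else NULL
      pc <- generateStemCloud(stemCloudSpec(
        dbh = tr$dbh[i], height = tr$height[i],
        radialNoiseSd = radialNoiseSd, pointsPerM = pointsPerM,
        crown = crown, center = c(tr$x[i], tr$y[i])))
      cc <- coords(pc)
      cc[, "z"] <- cc[, "z"] +
        groundSlope[1] * tr$x[i] + groundSlope[2] * tr$y[i]
      cbind(cc, treeId = tr$tree_id[i], trueGround = 0)
    })
    if (ground) {
      L <- plotSize(stand)
      g <- expand.grid(x = seq(0, L, by = groundSpacing),
                       y = seq(0, L, by = groundSpacing))
      gz <- groundSlope[1] * g$x + groundSlope[2] * g$y
      parts <- c(parts, list(cbind(x = g$x, y = g$y, z = gz,
                                   treeId = NA_real_, trueGround = 1)))
    }
    all <- do.call(rbind, parts)
    PointCloud(all[, c("x", "y", "z")],
               pointData = data.frame(treeId = all[, "treeId"],
                                      trueGround = all[, "trueGround"] == 1),
               metadata = list(plotSize = plotSize(stand)))
  })
}

#' Generate paired field / scanner-derived measurement tables
#'
#' Produces an estimated value for each tree as `field - bias + noise`, so
#' the evaluation module's bias statistic (field minus estimate) recovers
#' `+bias` in expectation: a positive injected bias emulates the systematic
#' underestimation typical of under-canopy laser scanning.
#'
#' @param stand a [ForestStand-class] whose `dbh`/`height` are the field
#'   truth.
#' @param biasDbh,biasTh injected underestimation of DBH (cm) and total
#'   height (m).
#' @param noiseSdDbh,noiseSdTh Gaussian measurement noise (cm, m); must be
#'   non-negative.
#' @param seed integer seed.
#' @return data.frame with columns `tree_id`, `dbh_field`, `dbh_est`,
#'   `height_field`, `height_est`.
#' @export
generatePairedMeasurements <- function(stand, biasDbh = 0, biasTh = 0,
                                       noiseSdDbh = 0, noiseSdTh = 0,
                                       seed = NULL) {
  stopifnot(is(stand, "ForestStand"))
  tr <- treeData(stand)
  if (nrow(tr) == 0) stop("stand is empty")
  if (noiseSdDbh < 0 || noiseSdTh < 0) stop("noise sd must be >= 0")
  .withSeed(seed, {
    n <- nrow(tr)
    data.frame(tree_id = tr$tree_id,
               dbh_field = tr$dbh,
               dbh_est = tr$dbh - biasDbh + stats::rnorm(n, 0, noiseSdDbh),
               height_field = tr$height,
               height_est = tr$height - biasTh + stats::rnorm(n, 0, noiseSdTh))
  })
}
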