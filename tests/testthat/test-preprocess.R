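test_that("cropToPlot keeps exactly the in-plot points, boundary included", {
  pc <- PointCloud(cbind(x = c(0.5, 2, 0, 1), y = c(0.5, 2, 0, 0.5), z = 0))
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  out <- cropToPlot(pc, sq)
  expect_equal(npoints(out), 3) # (0.5,0.5), corner (0,0), edge (1,0.5)
  inside <- PointCloud(cbind(x = runif(50, 0.1, 0.9),
                             y = runif(50, 0.1, 0.9), z = 0))
  expect_equal(npoints(cropToPlot(inside, sq)), 50)
  expect_error(cropToPlot(pc, cbind(c(0, 1, 2, 3), c(0, 1, 2, 3))),
               "degenerate")
})

test_that("cropToPlot agrees with a half-plane oracle on a rotated plot", {
  set.seed(21)
  th <- pi / 7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  sq <- t(R %*% t(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))) + 2
  pts <- cbind(x = runif(400, -5, 15), y = runif(400, -5, 15), z = 0)
  got <- npoints(cropToPlot(PointCloud(pts), sq))
  want <- sum(convexContains(pts[, 1], pts[, 2], sq[, 1], sq[, 2]))
  expect_equal(got, want)
  # idempotence
  pc1 <- cropToPlot(PointCloud(pts), sq)
  expect_identical(coords(cropToPlot(pc1, sq)), coords(pc1))
})

test_that("randomSample keeps the right count, order and inclusion rate", {
  pc <- PointCloud(cbind(x = seq_len(1000), y = 0, z = 0))
  expect_identical(coords(randomSample(pc, 1.0, seed = 1)), coords(pc))
  s <- randomSample(pc, 0.8, seed = 1)
  expect_equal(npoints(s), 800)
  expect_true(!is.unsorted(coords(s)[, "x"])) # survivors keep input order
  expect_identical(coords(randomSample(pc, 0.8, seed = 7)),
                   coords(randomSample(pc, 0.8, seed = 7)))
  # per-point inclusion frequency over seeded replicates
  small <- PointCloud(cbind(x = seq_len(50), y = 0, z = 0))
  hits <- numeric(50)
  for (r in seq_len(2000)) {
    kept <- coords(randomSample(small, 0.8, seed = r))[, "x"]
    hits[kept] <- hits[kept] + 1
  }
  expect_true(all(abs(hits / 2000 - 0.8) < 0.03))
})

test_that("SOR removes a gross outlier and spares equal-statistic points", {
  # uniformly spaced circle: every point's mean-kNN distance is identical
  # by symmetry, so nothing may be removed
  th <- 2 * pi * (0:99) / 100
  ring <- PointCloud(cbind(x = 5 * cos(th), y = 5 * sin(th), z = 0))
  expect_equal(npoints(sorDenoise(ring)), 100)
  withOut <- PointCloud(cbind(x = c(5 * cos(th), 100),
                              y = c(5 * sin(th), 100), z = 0))
  den <- sorDenoise(withOut)
  expect_equal(npoints(den), 100)
  expect_equal(cloudMetadata(den)$sorRemoved, 1)
  expect_true(max(coords(den)[, "x"]) < 100)
  # second pass is a no-op
  den2 <- sorDenoise(den)
  expect_identical(coords(den2), coords(den))
  expect_error(sorDenoise(ring, k = 100), "k")
})

test_that("ground classification recovers planar terrain under stems", {
  g <- expand.grid(x = seq(0, 10, 0.5), y = seq(0, 10, 0.5))
  stems <- expand.grid(x = c(2, 7), y = c(3, 8), z = seq(0.3, 5, 0.1))
  flat <- PointCloud(cbind(x = c(g$x, stems$x), y = c(g$y, stems$y),
                           z = c(rep(0, nrow(g)), stems$z)))
  cl <- classifyGround(flat)
  lab <- pointData(cl)$classification
  expect_equal(length(lab), npoints(flat)) # every point labelled
  expect_true(all(lab[coords(cl)[, "z"] == 0] == 2L))
  expect_true(all(lab[coords(cl)[, "z"] >= 0.3] == 1L))
  # tilted plane
  tilt <- PointCloud(cbind(x = c(g$x, stems$x), y = c(g$y, stems$y),
                           z = c(0.1 * g$x, 0.1 * stems$x + stems$z)))
  labT <- pointData(classifyGround(tilt))$classification
  truth <- c(rep(TRUE, nrow(g)), rep(FALSE, nrow(stems)))
  expect_gt(mean((labT == 2L) == truth), 0.99)
  # single point
  one <- classifyGround(PointCloud(cbind(x = 1, y = 1, z = 5)))
  expect_equal(pointData(one)$classification, 2L)
})

test_that("TIN DEM reproduces a plane exactly and matches vertices", {
  plane <- function(x, y) 2 + 0.3 * x - 0.2 * y
  tri3 <- PointCloud(cbind(x = c(0, 10, 0), y = c(0, 0, 10),
                           z = plane(c(0, 10, 0), c(0, 0, 10))))
  dem3 <- buildDEM(tri3)
  qx <- runif(20, 0, 4); qy <- runif(20, 0, 4)
  expect_equal(demElevation(dem3, qx, qy), plane(qx, qy), tolerance = 1e-12)
  set.seed(31)
  gx <- runif(60, 0, 10); gy <- runif(60, 0, 10)
  dem <- buildDEM(PointCloud(cbind(x = gx, y = gy, z = plane(gx, gy))))
  expect_equal(demElevation(dem, gx, gy), plane(gx, gy), tolerance = 1e-9)
  qx <- runif(100, 0, 10); qy <- runif(100, 0, 10)
  expect_lt(max(abs(demElevation(dem, qx, qy) - plane(qx, qy))), 1e-9)
  expect_error(buildDEM(PointCloud(cbind(x = 1:5, y = 1:5, z = 0))),
               "collinear")
})

test_that("height normalization flattens terrain and preserves xy", {
  plane <- function(x, y) 1 + 0.1 * x + 0.05 * y
  set.seed(32)
  gx <- runif(80, 0, 10); gy <- runif(80, 0, 10)
  ground <- PointCloud(cbind(x = gx, y = gy, z = plane(gx, gy)))
  dem <- buildDEM(ground)
  norm <- normalizeHeights(ground, dem)
  expect_equal(max(abs(coords(norm)[, "z"])), 0, tolerance = 1e-9)
  expect_identical(coords(norm)[, c("x", "y")], coords(ground)[, c("x", "y")])
  # a stem on tilted ground becomes vertical with base at 0
  stem <- PointCloud(cbind(x = 5, y = 5, z = plane(5, 5) + seq(0, 6, 0.1)))
  ns <- normalizeHeights(stem, dem)
  expect_equal(min(coords(ns)[, "z"]), 0, tolerance = 1e-9)
  expect_equal(max(coords(ns)[, "z"]), 6, tolerance = 1e-9)
  # flat zero DEM is idempotent
  flat <- buildDEM(PointCloud(cbind(x = c(0, 10, 0, 10), y = c(0, 0, 10, 10),
                                    z = 0)))
  once <- normalizeHeights(stem, flat)
  expect_identical(coords(normalizeHeights(once, flat)), coords(once))
})

test_that("XYZ round trip preserves coordinates and attributes", {
  pc <- PointCloud(cbind(x = runif(10), y = runif(10), z = runif(10)),
                   pointData = data.frame(classification = rep(1:2, 5)))
  f <- tempfile(fileext = ".csv")
  writeXYZ(pc, f)
  back <- readXYZ(f)
  expect_equal(coords(back), coords(pc), tolerance = 1e-12)
  expect_equal(pointData(back)$classification, pointData(pc)$classification)
})
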