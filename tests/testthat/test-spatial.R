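test_that("edge buffer partitions trees like a distance-to-edge oracle", {
  df <- data.frame(tree_id = 1:3, species = "a",
                   x = c(1.0, 12.5, 23.0), y = c(12.0, 12.5, 24.0),
                   dbh = 10, height = 5)
  st <- applyEdgeBuffer(smallStand(df), 2.5)
  expect_equal(treeData(st)$core, c(FALSE, TRUE, FALSE))
  set.seed(41)
  rnd <- generateStand(standSpec(nTrees = 150, seed = 41))
  got <- treeData(applyEdgeBuffer(rnd, 2.5))
  edgeDist <- pmin(got$x, got$y, 25 - got$x, 25 - got$y)
  expect_equal(got$core, edgeDist >= 2.5)
  expect_error(applyEdgeBuffer(rnd, 13), "buffer")
})

test_that("neighbour search matches an exhaustive sort and conventions", {
  df <- data.frame(tree_id = 1:5, species = "a",
                   x = c(0, 1, 2, 3, 10), y = 0, dbh = 10, height = 5)
  u <- findNeighbors(smallStand(df, plotSize = 30), central = 1, k = 4)
  expect_setequal(u$neighbor_id, 2:5)
  expect_equal(u$distance, c(1, 2, 3, 10))
  # azimuth convention: north = 0, east = 90
  dfc <- data.frame(tree_id = 1:5, species = "a",
                    x = c(5, 5, 6, 5, 4), y = c(5, 6, 5, 4, 5),
                    dbh = 10, height = 5)
  uc <- findNeighbors(smallStand(dfc, plotSize = 10), central = 1, k = 4)
  expect_equal(uc$azimuth[match(2:5, uc$neighbor_id)], c(0, 90, 180, 270))
  # brute-force oracle on a 200-tree stand
  st <- generateStand(standSpec(nTrees = 200, seed = 42))
  tr <- treeData(st)
  for (cid in sample(tr$tree_id, 25)) {
    u <- findNeighbors(st, cid, 4)
    i <- match(cid, tr$tree_id)
    d <- sqrt((tr$x - tr$x[i])^2 + (tr$y - tr$y[i])^2)
    d[i] <- Inf
    want <- tr$tree_id[order(d, tr$tree_id)][1:4]
    expect_equal(u$neighbor_id, want)
  }
  # coincident stems are an error
  dup <- data.frame(tree_id = 1:5, species = "a",
                    x = c(1, 1, 3, 4, 5), y = 1, dbh = 10, height = 5)
  expect_error(findNeighbors(smallStand(dup, 10), 1), "coincident")
})

test_that("uniform angle index follows the strict 72-degree rule", {
  expect_equal(uniformAngle(c(0, 90, 180, 270)), 0)
  expect_equal(uniformAngle(c(0, 72, 144, 216)), 0) # gaps 72,72,72,144
  expect_equal(uniformAngle(c(0, 60, 120, 180)), 0.75)
  expect_equal(uniformAngle(c(10, 20, 30, 40)), 1) # folded reflex gap 30
  expect_error(uniformAngle(c(0, NA, 90, 180)), "azimuth")
})

test_that("mingling and dominance count strict differences", {
  expect_equal(mingling("a", rep("a", 4)), 0)
  expect_equal(mingling("a", c("b", "c", "d", "e")), 1)
  expect_equal(mingling("a", c("a", "a", "b", "c")), 0.5)
  expect_equal(dominance(30, c(10, 20, 25, 29)), 0)
  expect_equal(dominance(10, c(11, 20, 25, 29)), 1)
  expect_equal(dominance(20, c(20, 20, 20, 20)), 0) # ties are not larger
})

test_that("Hegyi index matches hand evaluation and scaling laws", {
  expect_equal(hegyi(20, 20, 1), 1)
  expect_equal(hegyi(20, rep(20, 4), rep(2, 4)), 2)
  expect_equal(hegyi(20, c(10, 20, 30, 40), c(2, 4, 5, 8)), 1.05)
  expect_error(hegyi(0, 10, 1), "positive")
  expect_error(hegyi(10, 10, 0), "positive")
  # DBH-scale invariance and distance scaling on a whole stand
  st <- generateStand(standSpec(nTrees = 120, seed = 43))
  ci1 <- spatialIndices(st)$CI
  tr2 <- treeData(st); tr2$dbh <- tr2$dbh * 3.7
  expect_equal(spatialIndices(ForestStand(tr2, 25))$CI, ci1,
               tolerance = 1e-12)
  tr3 <- treeData(st); tr3$x <- tr3$x * 2; tr3$y <- tr3$y * 2
  ci3 <- spatialIndices(ForestStand(tr3, 50), buffer = 5)$CI
  expect_equal(ci3, ci1 / 2, tolerance = 1e-12)
})

test_that("grade distribution covers the five 0.25 levels", {
  g <- gradeDistribution(c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(unname(g), rep(0.2, 5))
  expect_equal(sum(g), 1)
  expect_equal(unname(gradeDistribution(rep(0.5, 7))), c(0, 0, 1, 0, 0))
  expect_error(gradeDistribution(numeric(0)))
  expect_error(gradeDistribution(c(0.3)), "grid")
})

test_that("per-stand indices stay on the grid with sane plot means", {
  st <- generateStand(standSpec(pattern = "cluster", nTrees = 150,
                                seed = 44))
  si <- spatialIndices(st)
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  expect_true(all(si$W %in% grid))
  expect_true(all(si$U %in% grid))
  expect_true(all(si$M %in% grid))
  expect_true(all(si$CI > 0))
  s <- plotStructureSummary(si)
  expect_true(all(s$means[c("W", "U", "M")] >= 0 &
                    s$means[c("W", "U", "M")] <= 1))
  expect_equal(sum(s$grades$W), 1)
})

test_that("class competition totals conserve the stand total", {
  st <- generateStand(standSpec(nTrees = 200, seed = 45))
  si <- spatialIndices(st)
  cc <- classCompetition(si)
  expect_equal(sum(cc$byClass$totalCI), sum(si$CI))
  expect_equal(cc$meanCI, mean(si$CI))
  # single-tree class: total equals that tree's CI
  one <- si[which.max(si$dbh), ]
  ccs <- classCompetition(si, width = 1000)
  expect_equal(ccs$byClass$totalCI[1], sum(si$CI))
  # dominant species subset runs and flags empty classes
  dom <- abundanceProfile(st)$species[1]
  ccd <- classCompetition(si, species = dom)
  expect_true(all(ccd$byClass$n[ccd$byClass$class %in%
                                  ccd$emptyClasses] == 0))
})

test_that("Voronoi adjacency is symmetric on random stands", {
  st <- generateStand(standSpec(nTrees = 60, seed = 46))
  adj <- voronoiUnits(st)
  for (id in names(adj))
    for (j in adj[[id]])
      expect_true(as.integer(id) %in% adj[[as.character(j)]])
})
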