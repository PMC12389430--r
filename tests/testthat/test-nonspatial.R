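test_that("richness indices match their closed forms", {
  expect_equal(patrickRichness(setNames(rep(3, 10), letters[1:10])), 10)
  expect_equal(patrickRichness(c(a = 5)), 1)
  expect_equal(round(margalefIndex(10, 52), 2), 2.28)
  expect_equal(round(margalefIndex(28, 166), 2), 5.28)
  expect_equal(margalefIndex(1, 100), 0)
  expect_error(margalefIndex(5, 1), "N")
})

test_that("Shannon and Simpson agree with the direct formulas", {
  expect_equal(shannonIndex(rep(25, 4)), log(4))
  expect_equal(shannonIndex(c(100)), 0)
  p <- c(0.5, 0.25, 0.25)
  expect_equal(shannonIndex(p * 400), -sum(p * log(p)), tolerance = 1e-12)
  expect_equal(round(shannonIndex(p * 400), 4), 1.0397)
  expect_equal(simpsonIndex(c(10)), 0)
  expect_equal(simpsonIndex(c(50, 50)), 0.5)
  q <- c(0.5, 0.3, 0.2)
  expect_equal(simpsonIndex(q * 1000), 1 - sum(q^2), tolerance = 1e-12)
  expect_equal(simpsonIndex(q * 1000), 0.62)
})

test_that("Pielou evenness is H over ln S, undefined for a monoculture", {
  expect_equal(pielouEvenness(log(6), 6), 1)
  e <- pielouEvenness(1.65, 10)
  expect_equal(round(e, 4), 0.7166)
  expect_gte(e, 0.71)
  expect_warning(e1 <- pielouEvenness(0, 1), "single species")
  expect_true(is.nan(e1))
})

test_that("importance-value components match brute-force counting", {
  # monoculture: all components 100
  mono <- smallStand(data.frame(tree_id = 1:6, species = "a",
                                x = seq(2, 22, 4), y = seq(2, 22, 4),
                                dbh = 20, height = 8))
  cm <- importanceValueComponents(mono)
  expect_equal(unlist(cm[c("RA", "RF", "RD")]), c(RA = 100, RF = 100,
                                                  RD = 100))
  # two species, equal counts and DBH, both present in every quadrat
  g <- expand.grid(x = seq(2.5, 22.5, 5), y = seq(2.5, 22.5, 5))
  two <- smallStand(data.frame(
    tree_id = 1:50,
    species = rep(c("a", "b"), 25),
    x = rep(g$x, each = 2), y = rep(g$y, each = 2) + c(0, 0.5),
    dbh = 20, height = 8))
  ct <- importanceValueComponents(two)
  expect_equal(ct$RA, c(50, 50))
  expect_equal(ct$RF, c(50, 50))
  expect_equal(ct$RD, c(50, 50))
  # three-species stand against independent counting
  set.seed(51)
  st <- generateStand(standSpec(nTrees = 90, speciesCount = 3, seed = 51))
  tr <- treeData(st)
  comp <- importanceValueComponents(st, quadratSize = 5)
  for (s in comp$species) {
    sel <- tr$species == s
    expect_equal(comp$RA[comp$species == s], 100 * sum(sel) / nrow(tr))
    expect_equal(comp$RD[comp$species == s],
                 100 * sum(pi * (tr$dbh[sel] / 2)^2) /
                   sum(pi * (tr$dbh / 2)^2))
    quad <- paste(pmin(floor(tr$x / 5), 4), pmin(floor(tr$y / 5), 4))
    occ <- vapply(unique(tr$species),
                  function(u) length(unique(quad[tr$species == u])),
                  numeric(1))
    expect_equal(comp$RF[comp$species == s],
                 100 * occ[[s]] / sum(occ))
  }
  # closure: each component sums to 100
  expect_equal(sum(comp$RA), 100)
  expect_equal(sum(comp$RF), 100)
  expect_equal(sum(comp$RD), 100)
})

test_that("importance value is the mean of its three percent components", {
  expect_equal(round(importanceValue(39.13, 31.58, 40.30), 2), 37.00)
  expect_equal(importanceValue(100, 100, 100), 100)
  expect_equal(round(importanceValue(51.92, 41.67, 53.42), 2), 49.00)
  expect_error(importanceValue(120, 10, 10), "100")
  st <- generateStand(standSpec(nTrees = 120, seed = 52))
  iv <- importanceValueTable(st)
  expect_equal(sum(iv$IV), 100, tolerance = 1e-9)
  expect_true(!is.unsorted(rev(iv$IV)))
})

test_that("diameter classes use half-open 10 cm bins from 5 cm", {
  dc <- diameterClasses(c(8.97, 15.0, 5, 14.999, 25, 47))
  expect_equal(unname(dc$counts), c(3, 1, 1, 0, 1))
  expect_equal(names(dc$counts), c("I", "II", "III", "IV", "V"))
  expect_error(diameterClasses(c(10, 4)), "origin")
  # the bulk of a truncated-exponential stand declines class over class;
  # sparse extreme-diameter tails may carry isolated counts
  st <- generateStand(standSpec(nTrees = 1000, plotSize = 50, seed = 53))
  cs <- diameterClasses(st)$counts
  expect_true(all(diff(cs[1:5]) <= 0))
  expect_equal(sum(cs), 1000)
})

test_that("composition summary counts ranks through a taxonomy", {
  st <- smallStand(data.frame(tree_id = 1:6,
                              species = c("s1", "s2", "s3", "s1", "s2", "s3"),
                              x = seq(2, 22, 4), y = seq(2, 22, 4),
                              dbh = 10, height = 5))
  tax <- data.frame(species = c("s1", "s2", "s3"),
                    genus = c("g1", "g1", "g2"),
                    family = c("f1", "f1", "f1"))
  expect_equal(compositionSummary(st, tax),
               c(families = 1, genera = 2, species = 3))
  expect_warning(noTax <- compositionSummary(st, NULL), "taxonomy")
  expect_equal(unname(noTax), c(3, 3, 3))
  # partial taxonomy: unknown species counted as their own ranks
  expect_warning(part <- compositionSummary(st, tax[1:2, ]), "missing")
  expect_equal(part[["species"]], 3)
  expect_equal(part[["genera"]], 2) # g1 + unknown s3
  # generated stand with the deterministic synthetic taxonomy
  g <- generateStand(standSpec(nTrees = 200, speciesCount = 8, seed = 54))
  cs <- compositionSummary(g, syntheticTaxonomy(8))
  expect_true(cs[["families"]] <= cs[["genera"]])
  expect_true(cs[["genera"]] <= cs[["species"]])
})

test_that("diversity summary ties the indices together", {
  st <- generateStand(standSpec(nTrees = 150, speciesCount = 10, seed = 55))
  d <- diversitySummary(st)
  prof <- abundanceProfile(st)
  expect_equal(d$N, sum(prof$n))
  expect_equal(d$S, nrow(prof))
  expect_equal(d$shannon, -sum(prof$p * log(prof$p)), tolerance = 1e-12)
  expect_equal(d$simpson, 1 - sum(prof$p^2), tolerance = 1e-12)
  expect_equal(d$pielou, d$shannon / log(d$S))
  expect_true(d$simpson >= 0 && d$simpson < 1)
})
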