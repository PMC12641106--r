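test_that("generateTaxonomy is deterministic, rank-consistent, and shaped", {
  spec <- syntheticSpec(nClasses = 2, ordersPerClass = 2,
                        familiesPerOrder = 2, generaPerFamily = 3,
                        speciesGeomP = 0.25)
  a <- generateTaxonomy(spec, seed = 5)
  b <- generateTaxonomy(spec, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, generateTaxonomy(spec, seed = 6)))
  ## passes the package's own validation (nesting by construction)
  expect_silent(normalizeTaxonomy(a))
  expect_equal(length(unique(a$class)), 2)
  expect_equal(length(unique(a$order)), 4)
  expect_equal(length(unique(a$genus)), 24)
  ## every genus has at least one species
  expect_true(all(table(a$genus) >= 1))
})

test_that("a monogeneric spec collapses every pair weight to the congeneric step", {
  spec <- syntheticSpec(nClasses = 1, ordersPerClass = 1,
                        familiesPerOrder = 1, generaPerFamily = 1,
                        speciesGeomP = 0.2)
  tax <- generateTaxonomy(spec, seed = 2)
  if (nrow(tax) >= 2) {
    W <- weightMatrix(tax)
    expect_true(all(W[upper.tri(W)] == 1))
  }
  expect_equal(length(unique(tax$genus)), 1)
})

test_that("small geometric p concentrates species into few clades", {
  spec <- syntheticSpec(nClasses = 1, ordersPerClass = 1,
                        familiesPerOrder = 4, generaPerFamily = 2,
                        speciesGeomP = 0.1)
  tax <- generateTaxonomy(spec, seed = 9)
  shares <- sort(table(tax$family) / nrow(tax), decreasing = TRUE)
  ## the dominant family holds well over its even share of 25%
  expect_gt(shares[1], 0.35)
})

test_that("generated assemblages respect richness bounds and validate", {
  spec <- syntheticSpec(nClasses = 1, ordersPerClass = 3,
                        familiesPerOrder = 2, generaPerFamily = 3,
                        speciesGeomP = 0.15, nRegions = 5,
                        richnessRange = c(3, 20))
  tax <- generateTaxonomy(spec, seed = 4)
  x <- generateAssemblages(tax, spec, seed = 10)
  expect_s4_class(x, "TaxonOccurrence")
  r <- richness(x)
  expect_true(all(r >= 3 & r <= 20))
  rep <- validateDataset(taxonomyTable(x), presenceMatrix(x))
  expect_true(attr(rep, "ok"))
  expect_identical(presenceMatrix(generateAssemblages(tax, spec, seed = 10)),
                   presenceMatrix(x))
})

test_that("clustered mode at kappa = 1 stays within one family", {
  spec <- syntheticSpec(nClasses = 1, ordersPerClass = 2,
                        familiesPerOrder = 2, generaPerFamily = 3,
                        speciesGeomP = 0.05, nRegions = 8,
                        richnessRange = c(4, 8), modes = "clustered",
                        kappa = 1)
  tax <- generateTaxonomy(spec, seed = 21)
  x <- generateAssemblages(tax, spec, seed = 22)
  tab <- taxonomyTable(x)
  for (reg in regionNames(x)) {
    sp <- assemblage(x, reg)
    fams <- unique(tab$family[tab$species %in% sp])
    if (length(fams) == 1L)
      expect_lte(deltaPlus(tab, sp), 2)  # at most the confamilial step
  }
  ## at least most regions must be single-family under kappa = 1
  nfam <- vapply(regionNames(x), function(reg)
    length(unique(tab$family[tab$species %in% assemblage(x, reg)])),
    integer(1))
  expect_gte(mean(nfam == 1), 0.8)
})

test_that("overdispersed mode at kappa = 1 spans one species per order", {
  spec <- syntheticSpec(nClasses = 1, ordersPerClass = 4,
                        familiesPerOrder = 2, generaPerFamily = 2,
                        speciesGeomP = 0.2, nRegions = 6,
                        richnessRange = c(4, 4), modes = "overdispersed",
                        kappa = 1)
  tax <- generateTaxonomy(spec, seed = 31)
  x <- generateAssemblages(tax, spec, seed = 32)
  tab <- taxonomyTable(x)
  for (reg in regionNames(x)) {
    sp <- assemblage(x, reg)
    ## richness 4 = number of orders: exactly one species per order, so
    ## every pair shares only the class and scores the same-class step
    expect_equal(length(unique(tab$order[tab$species %in% sp])), 4)
    expect_equal(deltaPlus(tab, sp), 4)
  }
})

test_that("kappa = 0 reduces both structured modes to random draws", {
  base <- syntheticSpec(nClasses = 1, ordersPerClass = 3,
                        familiesPerOrder = 2, generaPerFamily = 2,
                        speciesGeomP = 0.15, nRegions = 1,
                        richnessRange = c(10, 10), kappa = 0)
  tax <- generateTaxonomy(base, seed = 41)
  draws <- function(modes) {
    spec <- base; spec$modes <- modes
    vapply(1:400, function(i) {
      x <- generateAssemblages(tax, spec, seed = i)
      deltaPlus(taxonomyTable(x), assemblage(x, "Region_1"))
    }, numeric(1))
  }
  dR <- draws("random"); dC <- draws("clustered")
  ## identical seeds and kappa = 0: the draws are literally the same
  expect_identical(dR, dC)
})

test_that("the frozen fixture validates and shows all three funnel flags", {
  fx <- paperLikeFixture()
  rep <- validateDataset(taxonomyTable(fx), presenceMatrix(fx))
  expect_true(attr(rep, "ok"))
  expect_equal(nrow(fx), 26)
  expect_equal(ncol(fx), 6)
  tab <- classifyRegions(groupDeltaTable(fx), fx, rownames(fx),
                         replicates = 2000, seed = 8)
  expect_setequal(unique(tab$flag),
                  c("above", "below", "within", "undefined"))
  ## regression-freeze the per-region Delta+ values of the fixture
  expect_equal(tab$deltaPlus[match(
    c("RadiationSea", "DispersedSea", "TypicalSea", "BroadSea", "PairSea"),
    tab$region)],
    c(1, 4.5, 168 / 45, 365 / 105, 3), tolerance = 1e-12)
})

test_that("structured draws fall back to uniform sampling instead of failing", {
  ## clustered richness beyond the focal family's size must still return a
  ## full assemblage (with a message), never an error
  spec <- syntheticSpec(nClasses = 1, ordersPerClass = 2,
                        familiesPerOrder = 2, generaPerFamily = 1,
                        speciesGeomP = 0.9, nRegions = 2,
                        richnessRange = c(3, 4), modes = "clustered",
                        kappa = 1)
  tax <- generateTaxonomy(spec, seed = 51)   # tiny families
  expect_no_error(suppressMessages({
    x <- generateAssemblages(tax, spec, seed = 52)
  }))
  expect_true(all(richness(x) >= 3))
})
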