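test_that("pairWeight returns the step of the lowest shared rank", {
  tab <- toyTaxonomy()
  w0 <- weightConvention("w0")
  ## congeners: 0 under the literal dialect, 1 under step1
  expect_equal(pairWeight(tab, "Hydrophis platurus", "Hydrophis major", w0), 0)
  expect_equal(pairWeight(tab, "Hydrophis platurus", "Hydrophis major"), 1)
  ## confamilial, different genera
  expect_equal(pairWeight(tab, "Hydrophis platurus", "Aipysurus laevis", w0), 1)
  ## same class only: a sea snake vs a sea turtle
  expect_equal(pairWeight(tab, "Hydrophis platurus", "Caretta caretta"), 4)
  ## different classes
  expect_equal(pairWeight(tab, "Caretta caretta", "Physeter macrocephalus"), 5)
  ## symmetry and error cases
  expect_equal(pairWeight(tab, "Caretta caretta", "Chelonia mydas"),
               pairWeight(tab, "Chelonia mydas", "Caretta caretta"))
  expect_error(pairWeight(tab, "Caretta caretta", "Caretta caretta"),
               "self-pair")
  expect_error(pairWeight(tab, "Caretta caretta", "Nessie"), "unknown")
})

test_that("weightMatrix matches per-pair oracle and is symmetric", {
  for (seed in 1:5) {
    tab <- randomSmallTaxonomy(10, seed = seed)
    W <- weightMatrix(tab)
    expect_true(isSymmetric(W))
    expect_equal(unname(diag(W)), rep(0, 10))
    prs <- combn(tab$species, 2)
    for (k in seq_len(ncol(prs)))
      expect_equal(W[prs[1, k], prs[2, k]],
                   oraclePairWeight(tab, prs[1, k], prs[2, k]))
  }
  expect_error(weightMatrix(toyTaxonomy(), rep("Caretta caretta", 2)),
               "duplicated")
})

test_that("deltaPlus equals the brute-force pair-enumeration oracle", {
  for (seed in 1:20) {
    tab <- randomSmallTaxonomy(12, seed = seed)
    set.seed(seed)
    s <- sample(2:8, 1)
    sp <- sample(tab$species, s)
    expect_equal(deltaPlus(tab, sp), oracleDelta(tab, sp),
                 tolerance = 1e-12)
    expect_equal(deltaPlus(tab, sp, weightConvention("w0")),
                 oracleDelta(tab, sp, w0 = TRUE), tolerance = 1e-12)
  }
})

test_that("deltaPlus agrees with vegan's taxondive on varying taxonomies", {
  skip_if_not_installed("vegan")
  ## vegan scales the deepest of the five steps to 100, so its Delta+ is
  ## exactly 20x the step1 value when every rank varies in the taxonomy
  tab <- taxonomyTable(paperLikeFixture())
  vt <- tab[, c("genus", "family", "order", "class")]
  rownames(vt) <- tab$species
  d <- vegan::taxa2dist(vt, varstep = FALSE)
  set.seed(42)
  comm <- matrix(rbinom(4 * nrow(tab), 1, 0.5), nrow = 4,
                 dimnames = list(paste0("r", 1:4), tab$species))
  td <- suppressWarnings(vegan::taxondive(comm, d))
  mine <- vapply(1:4, function(i)
    deltaPlus(tab, colnames(comm)[comm[i, ] == 1]), numeric(1))
  expect_equal(unname(td$Dplus), 20 * mine, tolerance = 1e-10)
})

test_that("dialect shift identity: step1 Delta+ = w0 Delta+ + 1 exactly", {
  for (seed in 1:10) {
    tab <- randomSmallTaxonomy(15, seed = seed)
    set.seed(seed + 100)
    sp <- sample(tab$species, sample(2:10, 1))
    expect_equal(deltaPlus(tab, sp),
                 deltaPlus(tab, sp, weightConvention("w0")) + 1,
                 tolerance = 1e-12)
  }
})

test_that("Delta+ is invariant under assemblage reordering", {
  tab <- randomSmallTaxonomy(12, seed = 3)
  sp <- tab$species[1:7]
  for (i in 1:5) {
    set.seed(i)
    expect_equal(deltaPlus(tab, sample(sp)), deltaPlus(tab, sp))
  }
})

test_that("all-congener assemblages sit at the congeneric step", {
  tab <- data.frame(species = sprintf("Hydrophis sp%d", 1:9),
                    genus = "Hydrophis", family = "Elapidae",
                    order = "Squamata", class = "Reptilia")
  for (s in 2:9)
    expect_equal(deltaPlus(tab, tab$species[1:s]), 1)
  expect_equal(deltaPlus(tab, tab$species, weightConvention("w0")), 0)
})

test_that("adding a species from a new order never lowers single-family Delta+", {
  tab <- toyTaxonomy()
  base <- c("Hydrophis platurus", "Hydrophis major", "Aipysurus laevis")
  d0 <- deltaPlus(tab, base)
  expect_gte(deltaPlus(tab, c(base, "Caretta caretta")), d0)
  expect_gte(deltaPlus(tab, c(base, "Physeter macrocephalus")), d0)
})

test_that("deltaPlus bounds and degenerate sizes", {
  tab <- toyTaxonomy()
  sp <- tab$species[1:5]
  W <- weightMatrix(tab, sp)
  off <- W[upper.tri(W)]
  d <- deltaPlus(tab, sp)
  expect_gte(d, min(off)); expect_lte(d, max(off))
  expect_error(deltaPlus(tab, sp[1]), "fewer than 2")
})

test_that("groupDeltaTable computes per-region values and undefined flags", {
  fx <- paperLikeFixture()
  tab <- groupDeltaTable(fx)
  expect_equal(nrow(tab), 6)
  ## a region holding everything reproduces the master-list Delta+
  tx <- taxonomyTable(fx)
  all1 <- matrix(1L, nrow(fx), 1, dimnames = list(rownames(fx), "ALL"))
  xall <- TaxonOccurrence(all1, tx)
  expect_equal(groupDeltaTable(xall)$deltaPlus, deltaPlus(tx, tx$species))
  ## single-species region undefined
  expect_equal(tab$flag[tab$region == "SparseSea"], "undefined")
  expect_true(is.na(tab$deltaPlus[tab$region == "SparseSea"]))
  ## eight congeners: Delta+ exactly the congeneric step
  expect_equal(tab$deltaPlus[tab$region == "RadiationSea"], 1)
  ## values match oracle per region
  for (r in c("DispersedSea", "TypicalSea", "BroadSea", "PairSea"))
    expect_equal(tab$deltaPlus[tab$region == r],
                 oracleDelta(tx, assemblage(fx, r)), tolerance = 1e-12)
  expect_error(groupDeltaTable(fx, "Genus_1_species_1"), "at least 2")
})

test_that("richnessTable sorts descending with canonical-order tie-break", {
  fx <- paperLikeFixture()
  rt <- richnessTable(fx)
  expect_equal(rt$richness, sort(colSums(presenceMatrix(fx)),
                                 decreasing = TRUE), ignore_attr = TRUE)
  ## tie between RadiationSea (8) and any 8-species region keeps column order
  expect_equal(rt$region[rt$richness == 8], "RadiationSea")
  ## restricted to a group absent everywhere: all zeros
  m <- presenceMatrix(fx)
  tx <- taxonomyTable(fx)
  m2 <- m; m2[tx$species[tx$genus == "Genus_9"], ] <- 0L
  fx2 <- TaxonOccurrence(m2, tx)
  expect_true(all(richnessTable(fx2, tx$species[tx$genus == "Genus_9"])$richness == 0))
})
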