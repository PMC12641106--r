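test_that("U agrees with the direct pair-counting definition, with ties", {
  set.seed(1)
  for (i in 1:25) {
    n1 <- sample(1:8, 1); n2 <- sample(1:8, 1)
    x <- sample(1:6, n1, replace = TRUE)   # heavy ties on purpose
    y <- sample(1:6, n2, replace = TRUE)
    res <- mannWhitneyU(x, y)
    expect_equal(res$U1, oracleU1(x, y))
    expect_equal(res$U1 + res$U2, n1 * n2)
    expect_equal(res$U, min(res$U1, res$U2))
  }
})

test_that("U matches exhaustive rank-arrangement enumeration for n1, n2 <= 6", {
  ## for every split of the untied ranks 1..N into groups of n1 and n2,
  ## the midrank formula must equal the pair-counting oracle
  for (n1 in c(2, 4, 6)) for (n2 in c(2, 5)) {
    N <- n1 + n2
    splits <- combn(N, n1)
    for (k in seq_len(ncol(splits))) {
      x <- splits[, k]; y <- setdiff(seq_len(N), x)
      res <- mannWhitneyU(x, y)
      expect_equal(res$U1, oracleU1(x, y))
      expect_equal(res$U1 + res$U2, n1 * n2)
    }
  }
})

test_that("z and p match the tie-corrected normal approximation in wilcox.test", {
  set.seed(7)
  for (i in 1:10) {
    x <- sample(1:10, 12, replace = TRUE)
    y <- sample(3:12, 9, replace = TRUE)
    res <- mannWhitneyU(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = FALSE))
    expect_equal(res$p, ref$p.value, tolerance = 1e-10)
    expect_equal(res$U1, unname(ref$statistic))
  }
})

test_that("degenerate and symmetric inputs behave as expected", {
  v <- c(2, 2, 2)
  res <- mannWhitneyU(v, v)
  expect_equal(res$z, 0); expect_equal(res$p, 1)
  ## identical multisets: U = n1*n2/2, z = 0
  x <- c(1, 2, 3, 4, 5)
  res2 <- mannWhitneyU(x, x)
  expect_equal(res2$U, 12.5)
  expect_equal(res2$z, 0)
  ## complete separation
  expect_equal(mannWhitneyU(c(1, 2), c(3, 4))$U, 0)
  expect_error(mannWhitneyU(numeric(0), 1), "non-empty")
})

test_that("permutation p converges to the exhaustive-split value", {
  x <- c(1, 2); y <- c(10, 11)
  exact <- oraclePermutationP(x, y)          # 1/3 over the 6 splits
  res <- monteCarloPermutation(x, y, B = 9999, seed = 5)
  expect_equal(res$p, exact, tolerance = 0.02)
  ## also for the mean statistic on a larger case
  set.seed(12)
  x2 <- rnorm(5); y2 <- rnorm(4) + 0.5
  exact2 <- oraclePermutationP(x2, y2, fn = mean)
  res2 <- monteCarloPermutation(x2, y2, "mean", B = 9999, seed = 6)
  expect_equal(res2$p, exact2, tolerance = 0.03)
})

test_that("permutation p is deterministic, bounded below, and symmetric", {
  x <- c(1, 3, 5, 7); y <- c(2, 4, 6, 20)
  a <- monteCarloPermutation(x, y, B = 999, seed = 3)
  b <- monteCarloPermutation(x, y, B = 999, seed = 3)
  expect_identical(a, b)
  expect_gte(a$p, 1 / 1000)
  swapped <- monteCarloPermutation(y, x, B = 9999, seed = 3)
  wide <- monteCarloPermutation(x, y, B = 9999, seed = 3)
  expect_equal(wide$p, swapped$p, tolerance = 0.02)  # MC noise only
  ## degenerate pooled sample
  expect_equal(monteCarloPermutation(c(1, 1), c(1, 1), B = 99)$p, 1)
  expect_error(monteCarloPermutation(x, y, B = 10), "B >= 99")
})

test_that("observed vs null: identical nulls give z = 0 and verdict random", {
  fx <- paperLikeFixture()
  tab <- groupDeltaTable(fx)
  ## ensemble whose pool per region is the observed assemblage itself:
  ## build it region by region so nulls reproduce the observed exactly
  tx <- taxonomyTable(fx)
  m <- presenceMatrix(fx)
  defined <- colnames(m)[colSums(m) >= 2]
  fakeTab <- do.call(rbind, lapply(1:3, function(k)
    data.frame(replicate = k, region = defined,
               richness = colSums(m)[defined],
               deltaPlus = tab$deltaPlus[match(defined, tab$region)])))
  ens <- methods::new("NullEnsemble",
                      matrices = list(m, m, m), deltaTable = fakeTab,
                      pool = rownames(m), seeds = c(1L, 2L, 3L))
  res <- observedVsNullTest(tab, ens, B = 199, seed = 1)
  expect_equal(res$mwu$z, 0)
  expect_equal(res$verdict, "random")
})

test_that("observed vs null detects strong clustering and sizes the samples", {
  fx <- paperLikeFixture()
  tab <- groupDeltaTable(fx)
  ens <- nullEnsemble(fx, k = 3, seed = 4)
  res <- observedVsNullTest(tab, ens, B = 499, seed = 2)
  expect_equal(res$nObs, 5)        # five defined regions in the fixture
  expect_equal(res$nNull, 15)      # three replicates of each
  expect_true(res$verdict %in% c("patterned", "random"))
  perRep <- observedVsNullTest(tab, ens, B = 499, seed = 2, pooled = FALSE)
  expect_length(perRep$perReplicate, 3)
  expect_error(observedVsNullTest(tab[tab$richness < 2, ], ens),
               "fewer than 2 regions")
})

test_that("type-I error of the combined verdict stays near alpha", {
  ## observed assemblages drawn from the same uniform null: the verdict
  ## should be "patterned" in roughly <= 5% of runs
  tab <- randomSmallTaxonomy(30, ngenus = 10, seed = 42)
  pool <- tab$species
  hits <- 0L
  nRuns <- 300L
  for (r in seq_len(nRuns)) {
    m <- matrix(0L, 30, 10,
                dimnames = list(pool, sprintf("R%02d", 1:10)))
    set.seed(5000 + r)
    for (j in 1:10) m[sample.int(30, sample(5:15, 1)), j] <- 1L
    x <- TaxonOccurrence(m, tab)
    res <- observedVsNullTest(groupDeltaTable(x),
                              nullEnsemble(x, k = 3, seed = 7000 + r),
                              B = 199, seed = r)
    if (res$verdict == "patterned") hits <- hits + 1L
  }
  ## binomial(300, 0.05) upper tail: allow up to ~9%
  expect_lt(hits / nRuns, 0.09)
})
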