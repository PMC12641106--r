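## Independent oracles, deliberately naive: straight per-pair rank walks
## and exhaustive enumeration, sharing no code with the package internals.

## weight of one pair by walking ranks bottom-up
oraclePairWeight <- function(tab, a, b, w0 = FALSE) {
  i <- which(tab$species == a); j <- which(tab$species == b)
  base <- if (w0) 0 else 1
  for (rk in c("genus", "family", "order", "class")) {
    if (tab[[rk]][i] == tab[[rk]][j]) return(base)
    base <- base + 1
  }
  base
}

## Delta+ by explicit enumeration of all unordered pairs
oracleDelta <- function(tab, sp, w0 = FALSE) {
  prs <- combn(sp, 2)
  mean(apply(prs, 2, function(p) oraclePairWeight(tab, p[1], p[2], w0)))
}

## a random but rank-consistent small taxonomy: nesting is guaranteed by
## deriving each parent label arithmetically from the genus id
randomSmallTaxonomy <- function(nsp, ngenus = 6, seed = 1) {
  set.seed(seed)
  g <- sample.int(ngenus, nsp, replace = TRUE)
  data.frame(species = sprintf("sp%02d", seq_len(nsp)),
             genus = sprintf("G%d", g),
             family = sprintf("F%d", (g - 1) %/% 2),
             order = sprintf("O%d", (g - 1) %/% 4),
             class = sprintf("C%d", (g - 1) %/% 8))
}

## exhaustive subset distribution of Delta+ at size s
oracleSubsetDeltas <- function(tab, pool, s, w0 = FALSE) {
  apply(combn(pool, s), 2, function(sub) oracleDelta(tab, sub, w0))
}

## U statistic by the direct pair-counting definition (ties count half)
oracleU1 <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

## exact two-sided permutation p for a location statistic by full split
## enumeration
oraclePermutationP <- function(x, y, fn = median) {
  pool <- c(x, y); n1 <- length(x)
  obs <- abs(fn(x) - fn(y))
  splits <- combn(length(pool), n1)
  stats <- apply(splits, 2, function(id) abs(fn(pool[id]) - fn(pool[-id])))
  mean(stats >= obs - 1e-12)
}

## a tiny valid taxonomy reused across files
toyTaxonomy <- function() {
  data.frame(
    species = c("Hydrophis platurus", "Hydrophis major",
                "Aipysurus laevis", "Caretta caretta",
                "Chelonia mydas", "Dermochelys coriacea",
                "Physeter macrocephalus"),
    genus = c("Hydrophis", "Hydrophis", "Aipysurus", "Caretta",
              "Chelonia", "Dermochelys", "Physeter"),
    family = c("Elapidae", "Elapidae", "Elapidae", "Cheloniidae",
               "Cheloniidae", "Dermochelyidae", "Physeteridae"),
    order = c("Squamata", "Squamata", "Squamata", "Testudines",
              "Testudines", "Testudines", "Cetacea"),
    class = c(rep("Reptilia", 6), "Mammalia"))
}
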