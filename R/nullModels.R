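## deterministic child-seed derivation: master seed plus a large prime
## stride per stream index, wrapped to stay a valid 32-bit integer
childSeed <- function(master, i) {
  as.integer((as.numeric(master) + 99991 * as.numeric(i)) %% 2147483647)
}

#' Randomization funnel for Delta+
#'
#' The null expectation of Delta+ for an assemblage of size s assembled at
#' random: draws \code{replicates} uniform subsets of size s without
#' replacement from the master pool, computes Delta+ of each, and returns
#' the replicate mean and the empirical central confidence limits
#' (type-7 interpolated quantiles at (1-level)/2 and 1-(1-level)/2).
#' Plotted against s these limits trace the classic funnel: wide at small
#' s, collapsing to zero width at s = pool size (the only subset is the
#' pool itself). Deterministic given \code{seed}.
#'
#' @param taxonomy taxonomy data.frame or [TaxonOccurrence-class].
#' @param pool character vector, the master species pool (>= 2).
#' @param s assemblage size(s), each in [2, length(pool)]; vectorized.
#' @param replicates number of random subsets per s (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @param conv a [weightConvention()].
#' @return data.frame with columns \code{s}, \code{mean}, \code{ciLower},
#'   \code{ciUpper}, \code{replicates}.
#' @examples
#' fx <- paperLikeFixture()
#' tdFunnel(fx, rownames(fx), s = c(3, 10), replicates = 200, seed = 1)
#' @export
tdFunnel <- function(taxonomy, pool, s, replicates = 10000, level = 0.95,
                     seed = 1L, conv = weightConvention()) {
  stopifnot(replicates >= 1, level > 0, level < 1)
  if (any(s < 2) || any(s > length(pool)))
    stop("each s must lie in [2, pool size]")
  W <- weightMatrix(taxonomy, pool, conv)
  n <- length(pool)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  out <- lapply(seq_along(s), function(k) {
    sk <- s[k]
    set.seed(childSeed(seed, k))
    if (sk == n) {
      d <- rep(.deltaFromW(W, seq_len(n)), 1L)
      vals <- c(mean = d, lo = d, hi = d)
    } else {
      reps <- vapply(seq_len(replicates), function(r)
        .deltaFromW(W, sample.int(n, sk)), numeric(1))
      q <- stats::quantile(reps, probs, names = FALSE, type = 7)
      vals <- c(mean = mean(reps), lo = q[1], hi = q[2])
    }
    data.frame(s = sk, mean = vals[["mean"]], ciLower = vals[["lo"]],
               ciUpper = vals[["hi"]], replicates = replicates)
  })
  do.call(rbind, out)
}

#' Classify regional Delta+ against the funnel
#'
#' Fills the funnel columns of a [groupDeltaTable()] result and flags each
#' region with s >= 2 as \code{"above"} if its Delta+ strictly exceeds the
#' upper confidence limit at its richness, \code{"below"} if strictly under
#' the lower limit, \code{"within"} otherwise (ties with a limit count as
#' within). Regions with s < 2 keep flag \code{"undefined"}. The funnel is
#' computed once per distinct richness value.
#'
#' A region above the funnel holds species more taxonomically remote from
#' one another than random assembly from the pool predicts
#' (overdispersion); below, more closely related (phylogenetic clustering).
#'
#' @param results data.frame from [groupDeltaTable()].
#' @param taxonomy taxonomy data.frame or [TaxonOccurrence-class].
#' @param pool master species pool for the funnel (typically the group's
#'   full species list).
#' @inheritParams tdFunnel
#' @return the results data.frame with funnel columns and flags filled.
#' @export
classifyRegions <- function(results, taxonomy, pool, replicates = 10000,
                            level = 0.95, seed = 1L,
                            conv = weightConvention()) {
  def <- which(results$richness >= 2)
  if (!length(def)) return(results)
  ss <- sort(unique(results$richness[def]))
  ss <- ss[ss <= length(pool)]
  fun <- tdFunnel(taxonomy, pool, ss, replicates, level, seed, conv)
  for (i in def) {
    row <- fun[fun$s == results$richness[i], ]
    if (!nrow(row)) next   # richness beyond pool: leave unclassified
    results$funnelMean[i] <- row$mean
    results$ciLower[i] <- row$ciLower
    results$ciUpper[i] <- row$ciUpper
    results$flag[i] <-
      if (results$deltaPlus[i] > row$ciUpper) "above"
      else if (results$deltaPlus[i] < row$ciLower) "below"
      else "within"
  }
  results
}

#' Richness-preserving randomization of an occurrence matrix
#'
#' For each region independently, draws as many species as the region
#' holds, uniformly without replacement from the master pool. Column sums
#' (per-region richness) are preserved exactly; row totals (range sizes)
#' are free — an unconstrained-row, fixed-column-sum null.
#'
#' @param occurrence 0/1 matrix (species x regions) or
#'   [TaxonOccurrence-class]; only its column sums and dimnames are used.
#' @param pool character vector of candidate species (the randomized matrix
#'   has these as its rows).
#' @param seed integer seed; draws are deterministic given it.
#' @return 0/1 integer matrix, rows = pool, columns as input.
#' @export
randomizeAssemblages <- function(occurrence, pool, seed = 1L) {
  m <- if (methods::is(occurrence, "TaxonOccurrence"))
    presenceMatrix(occurrence) else occurrence
  rich <- colSums(m)
  if (any(rich > length(pool)))
    stop("region richness exceeds pool size; cannot randomize")
  out <- matrix(0L, length(pool), ncol(m),
                dimnames = list(pool, colnames(m)))
  for (j in seq_len(ncol(m))) {
    set.seed(childSeed(seed, j))
    out[sample.int(length(pool), rich[j]), j] <- 1L
  }
  stopifnot(identical(unname(colSums(out)), unname(rich)))
  out
}

#' Generate an ensemble of null occurrence matrices
#'
#' Builds \code{k} independent richness-preserving randomizations of the
#' observed matrix (restricted to \code{pool}) and computes per-region
#' Delta+ of each; regions with fewer than 2 species are omitted from the
#' Delta+ table. Child seeds derive deterministically from the master seed,
#' so the whole ensemble is reproducible from one integer.
#'
#' @param x a [TaxonOccurrence-class] object.
#' @param pool master species pool; NULL = all species in \code{x}.
#' @param k number of null matrices (the study design uses 3).
#' @param seed master integer seed.
#' @param conv a [weightConvention()].
#' @return a [NullEnsemble-class] object.
#' @export
nullEnsemble <- function(x, pool = NULL, k = 3L, seed = 1L,
                         conv = weightConvention()) {
  stopifnot(k >= 1)
  m <- presenceMatrix(x)
  if (is.null(pool)) pool <- rownames(m)
  pool <- intersect(rownames(m), pool)
  sub <- m[pool, , drop = FALSE]
  W <- weightMatrix(x, pool, conv)
  seeds <- vapply(seq_len(k), function(i) childSeed(seed, 1000L + i),
                  integer(1))
  mats <- lapply(seeds, function(sd) randomizeAssemblages(sub, pool, sd))
  tab <- do.call(rbind, lapply(seq_len(k), function(i) {
    mm <- mats[[i]]
    rows <- lapply(colnames(mm), function(reg) {
      idx <- which(mm[, reg] == 1L)
      if (length(idx) < 2L) return(NULL)
      data.frame(replicate = i, region = reg, richness = length(idx),
                 deltaPlus = .deltaFromW(W, idx))
    })
    do.call(rbind, rows)
  }))
  if (is.null(tab))
    tab <- data.frame(replicate = integer(), region = character(),
                      richness = integer(), deltaPlus = numeric())
  methods::new("NullEnsemble", matrices = mats, deltaTable = tab,
               pool = pool, seeds = seeds)
}
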